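# Fixture builders shared across the suite. Everything is generated in code;
# expensive artefacts (featurised synthetic sets) are memoised per session.

make_record <- function(compound_id = "C1", target_id = "T1", pchembl = 7,
                        smiles = "CCO", confidence = 9L,
                        target_type = "single protein",
                        source = "literature", year = 2010L,
                        activity_comment = NA_character_,
                        duplicate_flag = FALSE,
                        validity_comment = NA_character_,
                        doc_id = "D1") {
  data.frame(compound_id = compound_id, smiles = smiles,
             target_id = target_id, pchembl = pchembl,
             confidence = confidence, target_type = target_type,
             source = source, year = year,
             activity_comment = activity_comment,
             duplicate_flag = duplicate_flag,
             validity_comment = validity_comment, doc_id = doc_id,
             stringsAsFactors = FALSE)
}

make_records <- function(n, target_id = "T1", doc_ids = c("D1", "D2"),
                         pchembl = NULL, years = 2010L, seed = 1) {
  withr::with_seed(seed, {
    if (is.null(pchembl)) pchembl <- round(runif(n, 4, 9), 2)
    make_record(compound_id = sprintf("C%03d", seq_len(n)),
                target_id = target_id, pchembl = pchembl,
                year = rep_len(years, n),
                doc_id = rep_len(doc_ids, n))
  })
}

# curated dataset + features from a small planted-signal generation;
# memoised so several test files can share one featurisation
.fixture_cache <- new.env(parent = emptyenv())

small_benchmark_fixture <- function(sigma = 0.25, drift = FALSE) {
  key <- sprintf("bench_%g_%d", sigma, drift)
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  sim <- generate_synthetic(synthetic_config(
    n_targets = 4L, n_compounds = 80L, density = 0.5, sigma = sigma,
    drift = drift, seed = 3L))
  ds <- curate(sim$records, curation_config(min_compounds_per_target = 5L,
                                            min_publications_per_target = 1L))
  ds <- attach_sequences(ds, sim$sequences)
  feats <- featurize_dataset(ds, n_bits = 256L, physchem = FALSE,
                             protein = TRUE)
  out <- list(sim = sim, dataset = ds, features = feats)
  .fixture_cache[[key]] <- out
  out
}

# the generator's default-scale study set (20 targets x 500 compounds,
# density 0.2, measurement noise 0.25), curated and featurised once per run
default_benchmark_fixture <- function(drift = FALSE) {
  key <- sprintf("default_%d", drift)
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  sim <- generate_synthetic(synthetic_config(sigma = 0.25, drift = drift,
                                             seed = 1L))
  ds <- attach_sequences(curate(sim$records), sim$sequences)
  feats <- featurize_dataset(ds, n_bits = 256L)
  out <- list(sim = sim, dataset = ds, features = feats)
  .fixture_cache[[key]] <- out
  out
}

# tiny deterministic prediction set over given pairs
make_predictions <- function(pairs, score, threshold = 6.5,
                             provenance = "model") {
  data.frame(compound_id = pairs$compound_id, target_id = pairs$target_id,
             score = score,
             predicted_class = ifelse(score >= threshold, "active",
                                      "inactive"),
             provenance = provenance, stringsAsFactors = FALSE)
}
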