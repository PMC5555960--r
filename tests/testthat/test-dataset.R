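test_that("read_activity_table maps columns, preserves missing fields and
           rejects missing mandatory columns", {
  raw <- data.frame(molregno = c("C1", "C2", "C3"),
                    canonical_smiles = c("CCO", "CCN", "CCC"),
                    accession = "T1",
                    pchembl_value = c("7.1", "", "5.2"),
                    confidence_score = 9L, target_type = "single protein",
                    source = "literature", year = 2010L,
                    activity_comment = c("", "inconclusive", ""),
                    data_validity_comment = "", potential_duplicate = 0L,
                    doc_id = "D1", stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(raw, path, row.names = FALSE)

  rec <- read_activity_table(path)
  expect_equal(nrow(rec), 3L)
  expect_true(is.na(rec$pchembl[2]))       # empty cell -> absent, not zero
  expect_true(is.na(rec$activity_comment[1]))
  expect_equal(rec$activity_comment[2], "inconclusive")
  expect_identical(rec$duplicate_flag, c(FALSE, FALSE, FALSE))

  expect_error(
    read_activity_table(raw[, setdiff(names(raw), "accession")]),
    "accession")
})

test_that("aggregate_duplicates takes the group median and documented
           provenance", {
  recs <- rbind(
    make_record("C1", "T1", 6.0, year = 2011L, doc_id = "D1"),
    make_record("C1", "T1", 7.0, year = 2009L, doc_id = "D2"),
    make_record("C1", "T1", 6.4, year = 2012L, doc_id = "D1"),
    make_record("C2", "T1", 5.0, doc_id = "D3"),
    make_record("C3", "T1", 5.0, doc_id = "D1"),
    make_record("C3", "T1", 6.0, doc_id = "D1"))
  agg <- aggregate_duplicates(recs)
  expect_equal(nrow(agg), 3L)
  expect_equal(agg$pchembl[agg$compound_id == "C1"], 6.4)  # odd group
  expect_equal(agg$pchembl[agg$compound_id == "C3"], 5.5)  # even: mean of mid
  expect_equal(agg$pchembl[agg$compound_id == "C2"], 5.0)  # singleton
  expect_equal(agg$year[agg$compound_id == "C1"], 2009L)   # earliest year
  expect_equal(agg$doc_id[agg$compound_id == "C1"], "D1;D2")
  expect_error(aggregate_duplicates(make_record(pchembl = NA_real_)),
               "finite pchembl")
})

test_that("curate applies row filters, then target-level count filters", {
  good <- make_records(35, target_id = "TKEEP", doc_ids = c("D1", "D2"))
  bad_comment <- make_record("CX", "TKEEP", 7, activity_comment = "Inconclusive")
  one_doc <- make_records(32, target_id = "TONEDOC", doc_ids = "D9")
  small <- make_records(10, target_id = "TSMALL", doc_ids = c("D3", "D4"))
  ds <- curate(rbind(good, bad_comment, one_doc, small))

  expect_s3_class(ds, "curated_dataset")
  expect_setequal(unique(ds$records$target_id), "TKEEP")
  expect_equal(nrow(ds$records), 35L)  # excluded comment dropped
  # row-filter mechanics
  flagged <- rbind(good,
                   make_record("CY", "TKEEP", 7, duplicate_flag = TRUE),
                   make_record("CZ", "TKEEP", 7, confidence = 8L),
                   make_record("CW", "TKEEP", 7,
                               validity_comment = "outside range"),
                   make_record("CV", "TKEEP", 7, source = "deposited"))
  expect_equal(nrow(curate(flagged)$records), 35L)
  # boundary: 29 distinct compounds is one short of the default 30
  expect_warning(
    empty <- curate(make_records(29, target_id = "T29",
                                 doc_ids = c("D1", "D2"))),
    "empty")
  expect_equal(nrow(empty$records), 0L)
})

test_that("curate is idempotent and one record per pair survives", {
  recs <- rbind(make_records(40, "TA", pchembl = seq(4, 9, length.out = 40)),
                make_records(40, "TB", seed = 2),
                make_record("C001", "TA", 6.9))  # duplicate pair
  ds1 <- curate(recs)
  key <- paste(ds1$records$compound_id, ds1$records$target_id)
  expect_false(anyDuplicated(key) > 0)
  ds2 <- curate(ds1$records)
  ord <- function(d) d[order(d$target_id, d$compound_id), ]
  expect_equal(ord(ds2$records), ord(ds1$records), ignore_attr = TRUE)
})

test_that("activity labelling is boundary-inclusive and strict on input", {
  expect_equal(label_activity(6.5, 6.5), "active")
  expect_equal(label_activity(6.49, 6.5), "inactive")
  expect_equal(label_activity(5.0, 5.0), "active")
  expect_equal(label_activity(c(7, 4), 6.5), c("active", "inactive"))
  expect_error(label_activity(NA_real_), "finite")
  expect_error(label_activity(Inf), "finite")
})

test_that("matrix_stats and dataset_stats do the completeness arithmetic", {
  # single cell: trivially complete
  expect_equal(matrix_stats(1, 1, 1)$completeness_pct, 100)
  ms <- matrix_stats(50, 200, 600)
  expect_equal(ms$completeness_pct * ms$matrix_size / 100, 600)

  recs <- rbind(make_records(40, "TA"), make_records(35, "TB", seed = 5))
  ds <- curate(recs, curation_config(min_compounds_per_target = 5))
  st <- dataset_stats(ds)
  expect_equal(st$n_targets, 2L)
  expect_equal(st$n_points, 75L)
  expect_equal(st$completeness_pct * st$matrix_size / 100, st$n_points)
  expect_equal(st$mean_compounds_per_target, 75 / 2)
  expect_equal(st$min_compounds_per_target, 35L)
  expect_error(dataset_stats(curate(make_records(3),
                                    curation_config(min_compounds_per_target = 5))),
               "empty") |> suppressWarnings()
})

test_that("murcko scaffolds count ring frameworks, not substituents", {
  expect_equal(murcko_scaffold("CCCCCC"), "")  # acyclic -> no framework
  expect_equal(murcko_scaffold("Cc1ccccc1"), murcko_scaffold("CCc1ccccc1"))
  expect_equal(count_murcko_scaffolds(
    c("c1ccccc1", "Cc1ccccc1", "c1ccncc1", "CCCC")), 2L)
})

test_that("random_split produces exact 10/27/63 partition sizes,
           reproducibly, preserving per-cell class balance", {
  sim <- generate_synthetic(synthetic_config(n_targets = 20L,
                                             n_compounds = 100L,
                                             density = 0.5, seed = 2L))
  ds <- curate(sim$records, curation_config(min_compounds_per_target = 2L,
                                            min_publications_per_target = 1L))
  n <- nrow(ds$records)
  expect_equal(n, 1000L)
  sp <- random_split(ds, seed = 42L)
  sizes <- table(sp$partition)
  expect_equal(unname(sizes[c("holdout", "test", "train")]),
               c(100L, 270L, 630L), ignore_attr = TRUE)
  # partition property: disjoint, exhaustive
  expect_setequal(sp$record_id,
                  paste(ds$records$compound_id, ds$records$target_id,
                        sep = "\r"))
  expect_identical(random_split(ds, seed = 42L), sp)
  expect_false(identical(random_split(ds, seed = 43L), sp))

  # stratification: train/test active fractions agree per sizeable target
  cls <- label_activity(ds$records$pchembl)
  key <- paste(ds$records$compound_id, ds$records$target_id, sep = "\r")
  for (part in c("train", "test")) {
    frac <- tapply(cls[key %in% sp$record_id[sp$partition == part]] == "active",
                   ds$records$target_id[key %in%
                                          sp$record_id[sp$partition == part]],
                   mean)
    assign(paste0("frac_", part), frac)
  }
  common <- intersect(names(frac_train), names(frac_test))
  expect_true(all(abs(frac_train[common] - frac_test[common]) < 0.10))

  expect_error(random_split(ds, 1, holdout_frac = 0.5, test_frac = 0.6),
               "fractions")
})

test_that("temporal_split cuts at the year boundary and flags empty sides", {
  recs <- rbind(make_records(3, "TA", years = 2011L),
                make_records(2, "TB", years = 2014L, seed = 2))
  ds <- curate(recs, curation_config(min_compounds_per_target = 1L,
                                     min_publications_per_target = 1L))
  sp <- temporal_split(ds, cutoff_year = 2013L)
  expect_equal(sum(sp$partition == "train"), 3L)
  expect_equal(sum(sp$partition == "test"), 2L)
  # boundary year goes to the test set
  recs2 <- rbind(make_records(2, "TA", years = 2012L),
                 make_records(2, "TB", years = 2013L, seed = 2))
  ds2 <- curate(recs2, curation_config(min_compounds_per_target = 1L,
                                       min_publications_per_target = 1L))
  sp2 <- temporal_split(ds2)
  expect_setequal(split_records(ds2, sp2, "test")$year, 2013L)
  expect_setequal(split_records(ds2, sp2, "train")$year, 2012L)

  all_old <- curate(make_records(5, years = 2010L),
                    curation_config(min_compounds_per_target = 1L,
                                    min_publications_per_target = 1L))
  expect_error(temporal_split(all_old), "test set empty")
  expect_error(temporal_split(all_old, cutoff_year = 2000L),
               "training set empty")
  ds_na <- all_old
  ds_na$records$year[1] <- NA_integer_
  expect_error(temporal_split(ds_na), "year")
})

test_that("pchembl thresholds convert to round nanomolar concentrations", {
  expect_equal(pchembl_to_nM(6.5), 300)
  expect_equal(pchembl_to_nM(5), 10000)
  expect_equal(pchembl_to_nM(9), 1)
})
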