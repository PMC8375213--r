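test_that("activity tables round-trip through CSV with optional columns", {
  path <- write_toy_activity_csv(c(
    "cmpd,target,pchembl,assay",
    "C1,T1,5.6,A1",
    "C1,T1,6.3,A2",
    "C2,T1,7.2,A1"))
  tab <- read_activity_table(path, list(compound_id = "cmpd",
                                        target_id = "target",
                                        p_activity = "pchembl",
                                        assay_id = "assay"))
  expect_s3_class(tab, "activity_table")
  expect_equal(nrow(tab), 3)
  expect_equal(tab$compound_id, c("C1", "C1", "C2"))
  expect_equal(tab$p_activity, c(5.6, 6.3, 7.2))
  expect_equal(tab$assay_id, c("A1", "A2", "A1"))

  out <- tempfile(fileext = ".csv")
  write_activity_table(tab, out)
  back <- read_activity_table(out, list(compound_id = "compound_id",
                                        target_id = "target_id",
                                        p_activity = "p_activity",
                                        assay_id = "assay_id"))
  expect_equal(as.data.frame(back), as.data.frame(tab),
               ignore_attr = TRUE)
})

test_that("rows with missing potency are skipped and counted; TSV is sniffed", {
  path <- write_toy_activity_csv(c(
    "cmpd\ttarget\tp",
    "C1\tT1\t5.0",
    "C2\tT1\tNA",
    "C3\tT1\tsix"))
  expect_message(
    tab <- read_activity_table(path, list(compound_id = "cmpd",
                                          target_id = "target",
                                          p_activity = "p")),
    "2 row\\(s\\)")
  expect_equal(nrow(tab), 1)
  expect_equal(attr(tab, "n_skipped"), 2)
})

test_that("missing mapped columns raise a configuration error naming them", {
  path <- write_toy_activity_csv(c("a,b,c", "1,2,3"))
  expect_error(
    read_activity_table(path, list(compound_id = "a", target_id = "b",
                                   p_activity = "potency")),
    "potency")
  expect_error(
    read_activity_table(path, list(compound_id = "a", p_activity = "c")),
    "target_id")
})

test_that("potencies outside 0-15 warn but are kept", {
  path <- write_toy_activity_csv(c("c,t,p", "C1,T1,42", "C2,T1,5"))
  expect_warning(
    tab <- read_activity_table(path, list(compound_id = "c",
                                          target_id = "t",
                                          p_activity = "p")),
    "outside 0-15")
  expect_equal(nrow(tab), 2)
})

test_that("replicate sd matches hand-computed values for both denominators", {
  tab <- data.frame(compound_id = c("C1", "C1", "C2", "C2", "C2",
                                    "C3", "C3", "C3"),
                    target_id = "T1",
                    p_activity = c(5.6, 6.3, 5, 5, 6, 5, 5, 5))
  res <- replicate_sd(tab, "cross_assay")
  expect_equal(res$table$n_replicates, c(2L, 3L, 3L))
  # {5.6, 6.3}: n-1 denominator
  expect_equal(res$table$sd[1], 0.4949747, tolerance = 1e-6)
  # {5, 5, 6}
  expect_equal(res$table$sd[2], 0.5773503, tolerance = 1e-6)
  # identical replicates
  expect_equal(res$table$sd[3], 0)
  expect_equal(res$median_sd, 0.4949747, tolerance = 1e-6)

  pop <- replicate_sd(tab, "cross_assay", denominator = "population")
  expect_equal(pop$table$sd[1], 0.35, tolerance = 1e-6)
})

test_that("aggregation keys control grouping; finer keys never enlarge groups", {
  tab <- data.frame(compound_id = rep("C1", 4), target_id = "T1",
                    p_activity = c(5, 6, 7, 8),
                    assay_id = c("A1", "A1", "A2", "A2"))
  coarse <- replicate_sd(tab, "cross_assay")
  fine <- replicate_sd(tab, "intra_assay")
  expect_equal(coarse$table$n_replicates, 4L)
  expect_equal(fine$table$n_replicates, c(2L, 2L))
  expect_true(all(fine$table$n_replicates <= max(coarse$table$n_replicates)))
  # custom scheme must always group by compound and target
  expect_error(aggregation_scheme("assay_id"), "compound_id")
})

test_that("replicate sd is invariant to record order; duplication doubles n only", {
  tab <- data.frame(compound_id = c("C1", "C1", "C2", "C2"),
                    target_id = "T1", p_activity = c(5.2, 6.1, 4.8, 5.9))
  shuffled <- tab[c(3, 1, 4, 2), ]
  expect_equal(replicate_sd(tab, "cross_assay")$table,
               replicate_sd(shuffled, "cross_assay")$table)
  # duplicating the whole table only changes group sizes: the population sd
  # is unchanged (the sample sd shrinks with its n-1 denominator)
  doubled <- replicate_sd(rbind(tab, tab), "cross_assay",
                          denominator = "population")
  orig <- replicate_sd(tab, "cross_assay", denominator = "population")
  expect_equal(doubled$table$n_replicates, 2L * orig$table$n_replicates)
  expect_equal(doubled$table$sd, orig$table$sd, tolerance = 1e-12)
})

test_that("no qualifying group yields an empty table and undefined median", {
  tab <- data.frame(compound_id = c("C1", "C2"), target_id = "T1",
                    p_activity = c(5, 6))
  expect_warning(res <- replicate_sd(tab, "cross_assay"), "no group")
  expect_equal(nrow(res$table), 0)
  expect_true(is.na(res$median_sd))
  expect_error(replicate_sd(tab, "cross_assay", min_replicates = 1),
               ">= 2")
})

test_that("feature matrices load in dense and sparse layouts and validate", {
  dense <- tempfile(fileext = ".csv")
  writeLines(c("compound_id,F1,F2,F3", "C1,1,0,0", "C2,0,1,0"), dense)
  expect_warning(read_feature_matrix(dense), "all-zero")
  m <- suppressWarnings(read_feature_matrix(dense))
  expect_equal(rownames(m), c("C1", "C2"))
  expect_equal(unname(m["C1", ]), c(1, 0, 0))

  sparse <- tempfile(fileext = ".csv")
  writeLines(c("row_id,feature_id,value", "C1,F1,1", "C2,F2,1", "C2,F3,1"),
             sparse)
  s <- read_feature_matrix(sparse, format = "sparse")
  expect_equal(s["C2", c("F2", "F3")], c(F2 = 1, F3 = 1))
  expect_equal(sum(s), 3)

  bad <- tempfile(fileext = ".csv")
  writeLines(c("compound_id,F1", "C1,2"), bad)
  expect_error(read_feature_matrix(bad), "exactly 0 or 1")
})
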