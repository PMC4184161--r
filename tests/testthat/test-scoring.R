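test_that("sample scoring thresholds digits strictly in panel order", {
  panel <- hla_panel()
  expect_identical(score_sample(c(28, 4182, 48), panel)$digits, "010")
  expect_identical(score_sample(c(45, 8041, 187), panel)$digits, "011")
  # strict inequality exactly at the threshold
  expect_identical(score_sample(c(128, 128, 128), panel)$digits, "000")
  expect_identical(score_sample(c(129, 128.5, 128.0001), panel)$digits, "111")

  # named intensities are matched to probes, not positions
  named <- c("209728_at" = 187, "203290_at" = 45, "213831_at" = 8041)
  expect_identical(score_sample(named, panel)$digits, "011")

  expect_error(score_sample(c("203290_at" = 1, "213831_at" = 2), panel),
               "209728_at")
  expect_error(score_sample(c(1, 2), panel), "expected 3")
})

test_that("a k-probe panel spans exactly 2^k score strings", {
  for (k in 1:3) {
    panel <- marker_panel(sprintf("pr%d", 1:k), 128)
    corners <- as.matrix(expand.grid(rep(list(c(4, 1000)), k)))
    scores <- apply(corners, 1L,
                    function(v) score_sample(unname(v), panel)$digits)
    expect_identical(length(unique(scores)), as.integer(2^k))
  }
})

test_that("sex calls follow the unanimous-panel rule", {
  panel <- redkx_panel()
  hi <- 1000; lo <- 10
  expect_identical(call_gender(c(hi, hi, hi, hi, lo), panel)$call, "M")
  expect_identical(call_gender(c(lo, lo, lo, lo, hi), panel)$call, "F")
  expect_identical(call_gender(c(hi, hi, hi, hi, hi), panel)$call,
                   "ambiguous")
  expect_identical(call_gender(c(hi, lo, lo, lo, hi), panel)$call,
                   "ambiguous")
  expect_error(call_gender(c("201909_at" = hi), panel), "204409_s_at")
})

test_that("donor consistency flags match the worked public example", {
  m <- fixture_matrix()
  ann <- fixture_annotation()
  scores <- score_samples(m, hla_panel())
  rep <- check_donor_consistency(scores, ann, hla_panel())

  get <- function(s, col) rep[[col]][rep$sample_id == s]
  # donor 45: one digit differs, intensity 187 within the soft band of 128
  expect_identical(get("GSM155495", "flag"), "SOFT")
  expect_match(get("GSM155495", "reasons"), "209728_at")
  # donor 35 time point 4: far-off intensities on two probes
  expect_identical(get("GSM155478", "flag"), "HARD")
  # concordant donors are clean
  expect_true(all(rep$flag[rep$donor_id %in% c("55", "54")] == "OK"))
  expect_true(all(rep$reasons[rep$flag == "OK"] == ""))
})

test_that("single-sample donors are annotated, not flagged", {
  panel <- marker_panel(c("a", "b"), 128)
  m <- matrix(c(1000, 1000), ncol = 1,
              dimnames = list(c("a", "b"), "only"))
  ann <- data.frame(sample_id = "only", donor_id = "solo",
                    stringsAsFactors = FALSE)
  rep <- check_donor_consistency(score_samples(m, panel), ann, panel)
  expect_identical(rep$flag, "OK")
  expect_identical(rep$note, "no repeat")
})

test_that("flags are invariant under sample-order permutation", {
  res <- simulate_and_flag(n_donors = 10, mixup_rate = 0.1, seed = 51)
  base <- res$report[order(res$report$sample_id), c("sample_id", "flag")]
  set.seed(52)
  for (i in 1:5) {
    perm <- sample(nrow(res$ds$annotation))
    ann_p <- res$ds$annotation[perm, , drop = FALSE]
    rep_p <- check_donor_consistency(res$scores, ann_p, res$panel)
    got <- rep_p[order(rep_p$sample_id), c("sample_id", "flag")]
    expect_identical(got$flag, base$flag)
  }
})

test_that("gender evidence escalates but never de-escalates flags", {
  m <- fixture_matrix()
  ann <- fixture_annotation()
  scores <- score_samples(m, hla_panel())
  rep <- check_donor_consistency(scores, ann, hla_panel())
  aug <- combine_with_gender(rep, ann[, c("sample_id", "gender_call")],
                             ann[, c("sample_id", "declared_sex")])

  get <- function(s, col) aug[[col]][aug$sample_id == s]
  # donor 35 TP1: female call among male siblings with declared M
  expect_identical(get("GSM155475", "flag"), "HARD")
  expect_match(get("GSM155475", "reasons"), "gender mismatch")
  # donor 32 TP2: called M, declared F -> both score and gender reasons
  expect_identical(get("GSM155472", "flag"), "HARD")
  expect_match(get("GSM155472", "reasons"), "gender mismatch")
  expect_match(get("GSM155472", "reasons"), "213831_at")
  # the SOFT flag of donor 45 is untouched by concordant gender
  expect_identical(get("GSM155495", "flag"), "SOFT")
  # no flag is ever lowered
  rank <- function(f) match(f, c("OK", "SOFT", "HARD"))
  expect_true(all(rank(aug$flag) >= rank(rep$flag)))

  # fully concordant calls leave flags and reasons unchanged
  concordant <- data.frame(sample_id = ann$sample_id,
                           gender_call = ann$declared_sex,
                           stringsAsFactors = FALSE)
  same <- combine_with_gender(rep, concordant,
                              ann[, c("sample_id", "declared_sex")])
  expect_identical(same$flag, rep$flag)

  # a SOFT sample with a gender mismatch becomes HARD
  flip <- concordant
  flip$gender_call[flip$sample_id == "GSM155495"] <- "M"
  hardened <- combine_with_gender(rep, flip,
                                  ann[, c("sample_id", "declared_sex")])
  expect_identical(hardened$flag[hardened$sample_id == "GSM155495"], "HARD")
})

test_that("dataset summary counts HARD flags by default, SOFT on request", {
  m <- fixture_matrix()
  ann <- fixture_annotation()
  scores <- score_samples(m, hla_panel())
  rep <- combine_with_gender(
    check_donor_consistency(scores, ann, hla_panel()),
    ann[, c("sample_id", "gender_call")],
    ann[, c("sample_id", "declared_sex")])

  s <- summarize_dataset(rep, ann)
  expect_identical(s$n_samples, 20L)
  expect_identical(s$n_donors_with_repeats, 5L)
  expect_identical(s$n_flagged, 3L)       # donor 35 x2 + donor 32 x1
  expect_identical(s$n_gender_fail, 2L)
  expect_identical(s$n_score_diff, 4L)    # includes donor 45's SOFT

  s_soft <- summarize_dataset(rep, ann, count_soft = TRUE)
  expect_identical(s_soft$n_flagged, 4L)
})

test_that("allele compatibility reflects the packaged match table", {
  expect_setequal(compatible_alleles(c(1, 0)),
                  c("HLA-DQA1*0401", "HLA-DQA1*0501"))
  expect_identical(compatible_alleles(c(0, 1), match_floor = 11),
                   "HLA-DQA1*0103")
  expect_length(compatible_alleles(c(1, 1), match_floor = 11), 0L)
  expect_error(compatible_alleles(c(2, 0)), "\\{0, 1\\}")
  # the packaged table has 7 alleles x 2 probe sets x 11 probes
  tab <- hla_dqa1_matches()
  expect_identical(nrow(tab), 14L)
  expect_identical(sum(grepl("^p[0-9]", names(tab))), 11L)
})
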