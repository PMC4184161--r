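test_that("generator is seed-reproducible and honest about truth", {
  cfg <- sim_config(n_donors = 8, samples_per_donor = 3,
                    n_probes_total = 40, n_bimodal = 5, seed = 61)
  a <- generate_dataset(cfg)
  b <- generate_dataset(cfg)
  expect_identical(a$matrix, b$matrix)
  expect_identical(a$annotation, b$annotation)
  expect_identical(a$truth, b$truth)

  # no mix-ups: annotation donor equals truth, zero swaps
  expect_identical(nrow(a$truth$swaps), 0L)
  expect_identical(a$annotation$donor_id,
                   rep(rownames(a$truth$states), each = 3))
})

test_that("donor-level states are shared by all of a donor's samples", {
  ds <- generate_dataset(sim_config(
    n_donors = 15, samples_per_donor = 4, n_probes_total = 10,
    n_bimodal = 6, sd_log2 = 0.4, n_gender_probes = 0, seed = 62))
  lg <- log2(ds$matrix)
  mid <- 7
  for (p in sprintf("bimodal_%03d", 1:6)) {
    state_of_sample <- lg[p, ] > mid
    per_donor <- split(state_of_sample, ds$annotation$donor_id)
    # every donor's samples fall on the same side of the midpoint ...
    expect_true(all(vapply(per_donor, function(s) all(s) || !any(s),
                           logical(1))))
    # ... and on the side the truth says
    donor_state <- vapply(per_donor, all, logical(1))
    expect_identical(unname(donor_state),
                     unname(ds$truth$states[names(per_donor), p]))
  }
})

test_that("high-state donor fraction matches the minor allele frequency", {
  ds <- generate_dataset(sim_config(
    n_donors = 200, samples_per_donor = 1, n_probes_total = 30,
    n_bimodal = 30, minor_allele_freq = 0.3, n_gender_probes = 0,
    seed = 63))
  frac <- colMeans(ds$truth$states)
  expect_true(all(abs(frac - 0.3) < 0.1))       # 3 sigma per probe
  expect_lt(abs(mean(frac) - 0.3), 0.02)
})

test_that("sex probes track donor sex", {
  ds <- generate_dataset(sim_config(
    n_donors = 30, samples_per_donor = 2, n_probes_total = 10,
    n_bimodal = 0, n_gender_probes = 5, frac_female = 0.5, seed = 64))
  lg <- log2(ds$matrix)
  male <- ds$truth$sex[ds$annotation$donor_id] == "M"
  expect_true(all(lg["gender_Y1", male] > 7))
  expect_true(all(lg["gender_Y1", !male] < 7))
  expect_true(all(lg["gender_XIST", !male] > 7))
  expect_true(all(lg["gender_XIST", male] < 7))
})

test_that("mix-up injection relabels the requested number of samples", {
  ann <- data.frame(sample_id = sprintf("s%03d", 1:100),
                    donor_id = rep(sprintf("d%02d", 1:25), each = 4),
                    stringsAsFactors = FALSE)
  none <- inject_mixups(ann, 0)
  expect_identical(none$annotation, ann)
  expect_identical(nrow(none$swaps), 0L)

  three <- inject_mixups(ann, 0.03, seed = 65)
  expect_identical(nrow(three$swaps), 3L)
  changed <- three$annotation$donor_id != ann$donor_id
  expect_identical(sum(changed), 3L)
  expect_true(all(three$swaps$recorded_donor_id !=
                    three$swaps$true_donor_id))

  solo <- data.frame(sample_id = c("a", "b"), donor_id = c("d", "d"),
                     stringsAsFactors = FALSE)
  expect_error(inject_mixups(solo, 0.5), "two donors")
  expect_error(inject_mixups(ann, 0.999), "every sample")
})

test_that("config validation lists every violated bound", {
  expect_error(sim_config(n_bimodal = 50, n_probes_total = 10,
                          minor_allele_freq = 0.9),
               "n_probes_total.*minor_allele_freq|minor_allele_freq.*n_probes_total")
  expect_error(sim_config(mode_low_log2 = 9, mode_high_log2 = 4),
               "mode_high_log2")
  expect_error(sim_config(mixup_rate = 1), "mixup_rate")
})

test_that("swap detection power grows with panel size", {
  # unconditional power: a 1-digit score leaves many swaps between
  # identically scored donors undetectable, so more panel probes mean
  # more swaps caught
  hits <- vapply(1:3, function(k) {
    found <- 0L
    total <- 0L
    for (seed in 1:12) {
      res <- simulate_and_flag(n_donors = 12, samples_per_donor = 3,
                               n_bimodal = k, mixup_rate = 0.06,
                               seed = 600 + seed)
      swaps <- res$ds$truth$swaps
      total <- total + nrow(swaps)
      for (i in seq_len(nrow(swaps))) {
        flag <- res$report$flag[res$report$sample_id == swaps$sample_id[i]]
        if (flag == "HARD") found <- found + 1L
      }
    }
    found / total
  }, numeric(1))
  expect_true(all(diff(hits) >= -0.05))  # monotone up to simulation noise
  expect_gt(hits[3], hits[1])
})
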