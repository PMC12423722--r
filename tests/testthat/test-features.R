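# Feature formulas, ratio combination, aggregation.

# direct-arithmetic oracle for the named formulas
oracle_features <- function(Aa, Ab, Ac, Ad, Ae, M, n_sys, H, pat) {
  list(age_index = (Ab - Ac - Ad - Ae) / Aa,
       age_index_v = (Ab - Ac - Ad) / Aa,
       P2O = M - n_sys,
       PAT2 = pat^2,
       H2_over_PAT2 = H^2 / pat^2,
       La = 0.8219 * H + 12.328,
       Lb = 0.2195 * H - 2.073)
}

fid_stub <- function(...) {
  base <- list(n_sys = 60L, A_sys = 0.9, n_notch = 120L, A_notch = 0.3,
               n_dia = 150L, A_dia = 0.4, n_ms = 25L, A_ms1 = 0.05,
               n_a = 10L, A_a2 = 1.2, n_b = 20L, A_b2 = -0.8,
               n_c = 30L, n_d = 40L, n_e = 118L, n_f = 130L,
               A_c2 = 0.15, A_d2 = -0.25, A_e2 = 0.1,
               n_R = -180L, M = 200L, usable = TRUE, missing = character(0))
  structure(utils::modifyList(base, list(...)), class = "fiducial_set")
}

test_that("ageing indices and P2O match direct arithmetic", {
  cyc <- as_cycle(numeric(200), n_R = -180L)
  cyc$M <- 200L
  f <- extract_ppg_features(cyc, fid_stub())
  expect_equal(unname(f["age_index"]), (-0.8 - 0.15 + 0.25 - 0.1) / 1.2)
  expect_equal(unname(f["age_index"]), -0.6667, tolerance = 1e-4)
  expect_equal(unname(f["age_index_v"]), (-0.8 - 0.15 + 0.25) / 1.2)
  expect_equal(unname(f["age_index_v"]), -0.5833, tolerance = 1e-4)
  expect_equal(unname(f["P2O"]), 140)

  # missing diastolic peak: its features are NA, the rest keep their values
  f2 <- extract_ppg_features(cyc, fid_stub(n_dia = NA_integer_,
                                           A_dia = NA_real_,
                                           missing = "diastolic"))
  expect_true(is.na(f2["n_dia"]) && is.na(f2["A_dia"]))
  expect_equal(unname(f2["P2O"]), 140)

  # near-zero A_a guards the division
  f3 <- extract_ppg_features(cyc, fid_stub(A_a2 = 1e-12))
  expect_true(is.na(f3["age_index"]))
})

test_that("WPD features report SI and component-to-forward intervals", {
  M <- 160
  th <- component_set(alpha = c(0.8, 0.5, 0.3, 0.2, 0.2),
                      beta = c(25, 40, 55, 95, 120),
                      gamma = c(7, 9, 11, 13, 15), M = M)
  d <- structure(list(theta_hat = th, n_pf = 30L, n_ps = 35L, n_pd = 95L,
                      M = M), class = "wpd")
  f <- extract_wpd_features(d)
  expect_equal(unname(f["SI"]), 60)
  expect_equal(unname(f["beta3_to_pf"]), 55 - 30)
  expect_equal(unname(f["beta4_to_pf"]), 95 - 30)
  expect_equal(unname(f[paste0("alpha", 1:5)]), th$alpha)
  d$n_pd <- NA_integer_
  expect_true(is.na(extract_wpd_features(d)["SI"]))
})

test_that("ECG features follow the negative-n_R sign convention", {
  cyc <- as_cycle(numeric(200), n_R = -180L)
  wf <- c(n_ps = 35, beta2 = 40)
  f <- extract_ecg_features(cyc, fid_stub(), height_cm = 170, wpd_features = wf)
  expect_equal(unname(f["PAT"]), 180)
  expect_equal(unname(f["PAT2"]), 32400)
  expect_equal(unname(f["H2_over_PAT2"]), 28900 / 32400)
  expect_equal(unname(f["H2_over_PAT2"]), 0.8920, tolerance = 1e-4)
  expect_equal(unname(f["R_to_ms"]), 25 - (-180))
  expect_equal(unname(f["R_to_ps"]), 35 - (-180))
  expect_equal(unname(f["R_to_beta2"]), 40 - (-180))
  # no R pairing: ECG features all missing
  f2 <- extract_ecg_features(cyc, fid_stub(n_R = NA_integer_), 170, wf)
  expect_true(all(is.na(f2)))
})

test_that("body-length approximations match the height formulas", {
  f <- compute_body_lengths(170, age = 60, weight_kg = 70)
  expect_equal(unname(f["La"]), 152.051)
  expect_equal(unname(f["Lb"]), 35.242)
  expect_equal(unname(f["La_minus_Lb"]), 116.809)
  expect_equal(unname(f["age2"]), 3600)
  f2 <- compute_body_lengths(160)
  expect_equal(unname(f2["La"]), 143.832)
  expect_equal(unname(f2["Lb"]), 33.047)
  expect_error(compute_body_lengths(0), "range")
  expect_error(compute_body_lengths(250), "range")
})

test_that("feature formulas agree with the oracle on randomized inputs", {
  set.seed(51)
  for (k in 1:25) {
    Aa <- runif(1, 0.5, 2); Ab <- runif(1, -1, 0); Ac <- runif(1, -0.5, 0.5)
    Ad <- runif(1, -0.5, 0); Ae <- runif(1, -0.2, 0.3)
    M <- sample(150:250, 1); n_sys <- sample(40:80, 1)
    H <- runif(1, 140, 200); pat <- sample(120:220, 1)
    orc <- oracle_features(Aa, Ab, Ac, Ad, Ae, M, n_sys, H, pat)
    cyc <- as_cycle(numeric(M), n_R = -pat); cyc$M <- M
    fid <- fid_stub(A_a2 = Aa, A_b2 = Ab, A_c2 = Ac, A_d2 = Ad, A_e2 = Ae,
                    n_sys = n_sys, n_R = -pat, M = M)
    fp <- extract_ppg_features(cyc, fid)
    fe <- extract_ecg_features(cyc, fid, H)
    fb <- compute_body_lengths(H)
    expect_equal(unname(fp["age_index"]), orc$age_index, tolerance = 1e-9)
    expect_equal(unname(fp["age_index_v"]), orc$age_index_v, tolerance = 1e-9)
    expect_equal(unname(fp["P2O"]), orc$P2O, tolerance = 1e-9)
    expect_equal(unname(fe["PAT2"]), orc$PAT2, tolerance = 1e-9)
    expect_equal(unname(fe["H2_over_PAT2"]), orc$H2_over_PAT2, tolerance = 1e-9)
    expect_equal(unname(fb["La"]), orc$La, tolerance = 1e-9)
    expect_equal(unname(fb["Lb"]), orc$Lb, tolerance = 1e-9)
  }
})

test_that("ratio combination spans ordered pairs and guards denominators", {
  v <- c(a = 4, b = 2, Age = 60, n_ms = 25)
  out <- combine_ratio_features(v)
  expect_equal(unname(out["a_over_b"]), 2)
  expect_equal(unname(out["Age_over_n_ms"]), 2.4)
  expect_length(out, 4 + 4 * 3)              # diagonal excluded
  # explicit pair spec
  out2 <- combine_ratio_features(v, pair_spec = cbind("Age", "n_ms"))
  expect_length(out2, 5)
  # missing or near-zero denominators propagate NA
  v2 <- c(x = 1, y = NA_real_, z = 1e-12)
  out3 <- combine_ratio_features(v2)
  expect_true(is.na(out3["x_over_y"]))
  expect_true(is.na(out3["x_over_z"]))
})

test_that("aggregation is median-within-sequence, mean-across-sequences", {
  s1 <- rbind(c(f1 = 10, f2 = 1), c(f1 = 12, f2 = NA), c(f1 = 100, f2 = 3))
  expect_equal(unname(aggregate_measurement(s1)["f1"]), 12)   # median, outlier-proof
  expect_equal(unname(aggregate_measurement(s1)["f2"]), 2)    # NA excluded
  two <- list(rbind(c(f1 = 12)), rbind(c(f1 = 14)))
  expect_equal(unname(aggregate_measurement(two)["f1"]), 13)  # mean of medians
  # feature present in one of three sequences: mean over the present median
  three <- list(rbind(c(f1 = 7)), rbind(c(f1 = NA_real_)), rbind(c(f1 = NA_real_)))
  expect_equal(unname(aggregate_measurement(three)["f1"]), 7)
})

test_that("median aggregation resists 40% outlier corruption", {
  set.seed(52)
  clean <- matrix(rnorm(20, mean = 50, sd = 2), ncol = 1,
                  dimnames = list(NULL, "f"))
  corrupted <- clean
  corrupted[1:8, 1] <- 1000                  # 40% of 20 cycles
  delta <- abs(aggregate_measurement(corrupted)["f"] -
               aggregate_measurement(clean)["f"])
  expect_lte(unname(delta), stats::IQR(clean))
})

test_that("the catalog registers every feature named in the method", {
  cat <- feature_catalog()
  expect_false(any(duplicated(cat$id)))
  needed <- c("P2O", "SI", "PAT", "PAT2", "H2_over_PAT2", "age_index",
              "age_index_v", "A_c2", "A_d2", "A_e2", "age", "age2", "La",
              "Lb", "La_minus_Lb", "R_to_ms", "R_to_ps", "R_to_beta2")
  expect_true(all(needed %in% cat$name))
  pin <- function(id) cat$name[cat$id == id]
  expect_equal(pin(1), "P2O")
  expect_equal(pin(18), "A_c2")
  expect_equal(pin(19), "A_d2")
  expect_equal(pin(20), "A_e2")
  expect_equal(pin(23), "age")
  expect_equal(pin(51), "SI")
  expect_equal(pin(63), "age2")
  expect_setequal(unique(cat$family), c("PPG", "WPD", "ECG", "BASIC"))
})
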