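# PET quantification: final dose, %ID/g, reference ratios, condition ratios

make_pet <- function(n = 6, seed = 1) {
  set.seed(seed)
  base <- data.frame(
    animal = sprintf("m%02d", 1:n), condition = "baseline",
    c_striatum_L = runif(n, 0.5, 1.5), c_striatum_R = runif(n, 0.5, 1.5),
    c_cerebellum = runif(n, 0.4, 1.0),
    dose_initial = runif(n, 15, 20), dose_residual = runif(n, 0.2, 1),
    weight_g = runif(n, 20, 30)
  )
  dmf <- base
  dmf$condition <- "dmf"
  dmf$c_striatum_L <- base$c_striatum_L * runif(n, 1.0, 1.3)
  dmf$c_striatum_R <- base$c_striatum_R * runif(n, 1.0, 1.3)
  pet_table(rbind(base, dmf))
}

test_that("final dose is initial minus residual, with guards", {
  m <- pet_table(data.frame(animal = "a", condition = "baseline",
                            c_striatum_L = 1, c_striatum_R = 1,
                            c_cerebellum = 1, dose_initial = 18.5,
                            dose_residual = 0.5, weight_g = 25))
  expect_equal(final_dose(m), 18)
  m0 <- m; m0$dose_residual <- 0
  expect_equal(final_dose(pet_table(m0)), 18.5)
  bad <- m; bad$dose_residual <- 19
  expect_error(pet_table(bad), "dose_initial")
})

test_that("vectorized final dose equals the scalar loop", {
  m <- make_pet(8)
  got <- final_dose(m)
  for (i in seq_len(nrow(m))) {
    expect_equal(got[i], m$dose_initial[i] - m$dose_residual[i])
  }
})

test_that("%ID/g normalization identity and scaling laws hold", {
  m <- pet_table(data.frame(animal = "a", condition = "baseline",
                            c_striatum_L = 18 / 25, c_striatum_R = 18 / 25,
                            c_cerebellum = 18 / 25, dose_initial = 18.5,
                            dose_residual = 0.5, weight_g = 25))
  idg <- percent_id_per_g(m)
  expect_equal(idg$idg_striatum, 100)    # C equals dose per gram exactly
  m2 <- m; m2$c_striatum_L <- 2 * m2$c_striatum_L
  m2$c_striatum_R <- 2 * m2$c_striatum_R
  expect_equal(percent_id_per_g(pet_table(m2))$idg_striatum, 200)
  m3 <- m; m3$dose_initial <- 36.5       # doubled final dose halves %ID/g
  expect_equal(percent_id_per_g(pet_table(m3))$idg_striatum, 50)
})

test_that("%ID/g on random tables equals direct formula application", {
  m <- make_pet(10, seed = 2)
  idg <- percent_id_per_g(m)
  for (i in seq_len(nrow(m))) {
    fd <- m$dose_initial[i] - m$dose_residual[i]
    s <- (m$c_striatum_L[i] + m$c_striatum_R[i]) / 2
    expect_equal(idg$idg_striatum[i], 100 * s / (fd / m$weight_g[i]))
  }
})

test_that("reference ratio identities: uniform uptake, 1.4x contrast, calibration", {
  m <- make_pet(5, seed = 3)
  uniform <- m
  uniform$c_striatum_L <- uniform$c_striatum_R <- uniform$c_cerebellum
  expect_equal(reference_ratio(pet_table(uniform))$ratio,
               rep(1, nrow(uniform)))
  contrast <- m
  contrast$c_striatum_L <- contrast$c_striatum_R <- 1.4 * contrast$c_cerebellum
  expect_equal(reference_ratio(pet_table(contrast))$ratio,
               rep(1.4, nrow(contrast)))
  scaled <- m
  scaled[, c("c_striatum_L", "c_striatum_R", "c_cerebellum")] <-
    2.31 * scaled[, c("c_striatum_L", "c_striatum_R", "c_cerebellum")]
  expect_equal(reference_ratio(pet_table(scaled))$ratio,
               reference_ratio(m)$ratio, tolerance = 1e-12)
})

test_that("DMF over baseline ratios per animal match direct quotients", {
  m <- make_pet(7, seed = 4)
  r <- dmf_over_baseline(m)
  bl <- m[m$condition == "baseline", ]
  df <- m[m$condition == "dmf", ]
  for (i in seq_len(nrow(r))) {
    b <- bl[bl$animal == r$animal[i], ]
    d <- df[df$animal == r$animal[i], ]
    sb <- (b$c_striatum_L + b$c_striatum_R) / 2
    sd_ <- (d$c_striatum_L + d$c_striatum_R) / 2
    expect_equal(r$ratio_mbq[i], sd_ / sb)
    expect_equal(r$ratio_ref[i],
                 (sd_ / d$c_cerebellum) / (sb / b$c_cerebellum))
  }
  identical_cond <- m
  identical_cond[identical_cond$condition == "dmf",
                 c("c_striatum_L", "c_striatum_R", "c_cerebellum")] <-
    identical_cond[identical_cond$condition == "baseline",
                   c("c_striatum_L", "c_striatum_R", "c_cerebellum")]
  r1 <- dmf_over_baseline(pet_table(identical_cond))
  expect_equal(r1$ratio_mbq, rep(1, nrow(r1)))
  # a 14% uptake increase gives ratio 1.14
  up <- m
  up[up$condition == "dmf", c("c_striatum_L", "c_striatum_R")] <-
    1.14 * up[up$condition == "baseline", c("c_striatum_L", "c_striatum_R")]
  expect_equal(dmf_over_baseline(pet_table(up))$ratio_mbq,
               rep(1.14, 7), tolerance = 1e-12)
  mismatched <- m[-1, ]
  expect_error(dmf_over_baseline(pet_table(mismatched)), "exactly once")
})

test_that("activity unit round-trip is exact and %ID/g is unit consistent", {
  x <- c(0.37, 18.5, 500)
  expect_equal(uci_to_mbq(mbq_to_uci(x)), x, tolerance = 1e-12)
  expect_equal(mbq_to_uci(37), 1000)     # 1 mCi = 37 MBq
  # %ID/g unchanged when dose and concentration are both expressed in uCi
  m <- make_pet(4, seed = 5)
  m_uci <- m
  cols <- c("c_striatum_L", "c_striatum_R", "c_cerebellum",
            "dose_initial", "dose_residual")
  m_uci[, cols] <- mbq_to_uci(m_uci[, cols])
  expect_equal(percent_id_per_g(pet_table(m_uci))$idg_striatum,
               percent_id_per_g(m)$idg_striatum, tolerance = 1e-12)
})

test_that("PET tables round-trip through CSV with validation", {
  m <- make_pet(3, seed = 6)
  path <- tempfile(fileext = ".csv")
  utils::write.csv(as.data.frame(m), path, row.names = FALSE)
  back <- read_pet_csv(path)
  expect_s3_class(back, "pet_table")
  expect_equal(back$c_striatum_L, m$c_striatum_L, tolerance = 1e-9)
  unlink(path)
  expect_error(pet_table(data.frame(animal = "a")), "missing columns")
})
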