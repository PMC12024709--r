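test_that("montage presets wire the pads with zero net current", {
  a <- stimulus_montage("A")
  expect_equal(sum(a$pads$current_mA), 0)
  expect_equal(a$pads$current_mA[a$pads$location == "bath"], -2)
  expect_equal(a$reference, "C3")
  b <- stimulus_montage("B")
  expect_setequal(b$pads$location, c("Fp1", "Fp2", "O1", "O2"))
  expect_equal(sum(abs(b$pads$current_mA)), 4 * 0.7)
  expect_error(stimulus_montage("custom",
    pads = data.frame(location = c("C3", "C4"), polarity = c("anode", "cathode"),
                      width_cm = 5, height_cm = 5, current_mA = c(1, -0.5)),
    reference = "C3"), "sum to zero")
  expect_error(stimulus_montage("custom",
    pads = data.frame(location = c("C3", "C4"), polarity = c("anode", "cathode"),
                      width_cm = 5, height_cm = 5, current_mA = c(1, -1)),
    reference = "Oz"), "reference")
})

test_that("pad discretisation conserves current and sits on the inset sphere", {
  lay <- study_layout()
  for (cond in c("A", "B", "C")) {
    src <- pad_source_points(stimulus_montage(cond), lay,
                             forward_model_params(pad_grid = c(3, 3)))
    expect_lt(abs(sum(src$current_mA)), 1e-12)
    on_head <- src$pad != "bath"
    r <- sqrt(src$x[on_head]^2 + src$y[on_head]^2 + src$z[on_head]^2)
    expect_equal(r, rep(lay$sphere$radius - 2, sum(on_head)),
                 tolerance = 1e-9)
  }
  # 1 x 1 discretisation of condition B: one +/-0.7 mA source per pad
  s1 <- pad_source_points(stimulus_montage("B"), lay,
                          forward_model_params(pad_grid = 1))
  expect_equal(nrow(s1), 4)
  expect_equal(sort(s1$current_mA), c(-0.7, -0.7, 0.7, 0.7))
  # condition A at 1 x 1: two +1 mA anodes and one -2 mA bath sink
  sA <- pad_source_points(stimulus_montage("A"), lay,
                          forward_model_params(pad_grid = 1))
  expect_equal(sA$current_mA[sA$pad == "bath"], -2)
  expect_equal(sA$z[sA$pad == "bath"], -(lay$sphere$radius + 20))
  big <- stimulus_montage("custom",
    pads = data.frame(location = c("C3", "bath"),
                      polarity = c("anode", "cathode"),
                      width_cm = 60, height_cm = 5, current_mA = c(2, -2)),
    reference = "C3")
  expect_error(pad_source_points(big, lay), "hemisphere")
})

test_that("the monopole potential has the closed form and 1/r decay", {
  src <- data.frame(x = 0, y = 0, z = 0, current_mA = 1)
  # closed form: 1 mA at 50 mm in 0.5 S/m
  expect_equal(potential_at(c(50, 0, 0), src, 0.5),
               1e-3 / (4 * pi * 0.5 * 0.05) * 1e3, tolerance = 1e-12)
  v_r <- potential_at(c(30, 0, 0), src, 0.5)
  v_2r <- potential_at(c(60, 0, 0), src, 0.5)
  expect_equal(v_r / v_2r, 2, tolerance = 1e-12)
  # antisymmetric pair: zero on the equidistant plane
  pair <- data.frame(x = c(-10, 10), y = 0, z = 0, current_mA = c(1, -1))
  expect_equal(potential_at(c(0, 5, 3), pair, 0.5), 0, tolerance = 1e-12)
  expect_error(potential_at(c(0, 0, 0), src, 0.5), "singular")
})

test_that("superposition: joint simulation equals the sum of circuits", {
  lay <- study_layout()
  prm <- noiseless_params()
  mk <- function(loc, cur) stimulus_montage("custom",
    pads = data.frame(location = loc, polarity = ifelse(cur > 0, "anode", "cathode"),
                      width_cm = 5, height_cm = 5, current_mA = cur),
    reference = loc[1])
  joint <- pad_source_points(mk(c("Fp1", "O1", "Fp2", "O2"),
                                c(0.7, -0.7, 0.7, -0.7)), lay, prm)
  c1 <- pad_source_points(mk(c("Fp1", "O1"), c(0.7, -0.7)), lay, prm)
  c2 <- pad_source_points(mk(c("Fp2", "O2"), c(0.7, -0.7)), lay, prm)
  pts <- recording_grid(lay, "O1")
  w <- sweep(as.matrix(pts[, c("x_mm", "y_mm", "z_mm")]), 2,
             attr(pts, "origin"), "+")
  expect_equal(potential_at(w, joint, 0.5),
               potential_at(w, c1, 0.5) + potential_at(w, c2, 0.5),
               tolerance = 1e-9)
})

test_that("swapping polarity negates potentials, preserving |dV|", {
  lay <- study_layout()
  prm <- noiseless_params()
  b <- stimulus_montage("B")
  flip <- b
  flip$pads$current_mA <- -flip$pads$current_mA
  flip$pads$polarity <- rev(flip$pads$polarity)
  pts <- lay$positions
  sb <- pad_source_points(b, lay, prm)
  sf <- pad_source_points(flip, lay, prm)
  expect_equal(potential_at(pts, sf, 0.5), -potential_at(pts, sb, 0.5),
               tolerance = 1e-12)
  rb <- simulate_recordings(b, lay, prm)
  rf <- simulate_recordings(flip, lay, prm)
  expect_equal(rf$delta_v$delta_v_mV, rb$delta_v$delta_v_mV,
               tolerance = 1e-12)
})

test_that("surface dV decays monotonically with distance from a lone pad", {
  lay <- study_layout()
  m <- stimulus_montage("custom",
    pads = data.frame(location = c("T3", "bath"),
                      polarity = c("anode", "cathode"),
                      width_cm = 5, height_cm = 5, current_mA = c(2, -2)),
    reference = "T3")
  rec <- simulate_recordings(m, lay, noiseless_params())
  dv <- rec$delta_v
  # ring electrodes ordered outward from the T3 pad (36, 72, ..., 180 deg);
  # the bath sink is equidistant from every ring electrode, so the profile
  # reflects the pad's 1/r decay alone
  ring <- c("T5", "O1", "Oz", "O2", "T6", "T4")
  vals <- vapply(ring, function(e)
    dv$delta_v_mV[dv$electrode == e & dv$depth == "Z0"], numeric(1))
  # T5 is closest to the T3 pad; dV grows with distance from the reference
  # pad pickup, i.e. decays with proximity to the pad
  expect_true(all(diff(vals) > 0))
})

test_that("condition B noiseless output is mirror-symmetric and seeded
           runs reproduce", {
  lay <- study_layout()
  rec <- simulate_recordings(stimulus_montage("B"), lay, noiseless_params())
  dv <- rec$delta_v
  pairs <- list(c("F7", "F8"), c("F3", "F4"), c("T3", "T4"), c("C3", "C4"),
                c("T5", "T6"), c("P3", "P4"))
  for (p in pairs) {
    l <- dv$delta_v_mV[dv$electrode == p[1]]
    r <- dv$delta_v_mV[dv$electrode == p[2]]
    expect_equal(l, r, tolerance = 1e-9)
  }
  # symmetry oracle: reflecting every source across the mid-sagittal plane
  # leaves the potential at reflected points unchanged
  src <- pad_source_points(stimulus_montage("B"), lay, noiseless_params())
  refl <- src; refl$x <- -refl$x
  pts <- lay$positions
  ptsr <- pts; ptsr[, 1] <- -ptsr[, 1]
  expect_equal(potential_at(ptsr, refl, 0.5), potential_at(pts, src, 0.5),
               tolerance = 1e-12)
  # seeded determinism with noise on
  p1 <- forward_model_params(noise_cv = 0.05, seed = 42)
  r1 <- simulate_recordings(stimulus_montage("B"), lay, p1)
  r2 <- simulate_recordings(stimulus_montage("B"), lay, p1)
  expect_identical(r1$delta_v, r2$delta_v)
})

test_that("doubling the injected current doubles every noiseless dV", {
  lay <- study_layout()
  a1 <- stimulus_montage("A")
  a2 <- a1; a2$pads$current_mA <- 2 * a2$pads$current_mA
  r1 <- simulate_recordings(a1, lay, noiseless_params())
  r2 <- simulate_recordings(a2, lay, noiseless_params())
  expect_equal(r2$delta_v$delta_v_mV, 2 * r1$delta_v$delta_v_mV,
               tolerance = 1e-12)
})

test_that("noiseless condition A surface field peaks next to a pad", {
  lay <- study_layout()
  rec <- simulate_recordings(stimulus_montage("A"), lay, noiseless_params())
  tab <- build_field_table(rec, lay)
  z0 <- tab[tab$depth == "Z0" & !tab$electrode %in% rec$pads, ]
  peak <- z0$electrode[which.max(z0$ef_mV_per_mm)]
  adjacent_to_pad <- c("F7", "F3", "T3", "P3", "T5", "Cz",  # around C3
                       "F8", "F4", "T4", "P4", "T6")        # around C4
  expect_true(peak %in% adjacent_to_pad)
})
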