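test_that("default integrin graph carries the named bonds and hinge angles", {
  g <- build_default_integrin()
  expect_equal(g$theta, 45)
  expect_equal(g$phi, 140)
  expect_equal(sum(g$bonds$state == "intact"), 2L)
  expect_equal(sum(g$bonds$state == "latent"), 3L)
  expect_false(g$calf_contact)
  expect_setequal(g$bonds$pair[g$bonds$state == "intact"],
                  c("PRO381-ARG563", "SER367-SER551"))
  expect_equal(g$bonds$barrier_force[g$bonds$pair == "PRO381-ARG563"], 58)
  expect_equal(g$bonds$barrier_force[g$bonds$pair == "SER367-SER551"], 60)
  expect_equal(count_path_bonds(g, "tangential"), 2L)
  expect_equal(count_path_bonds(g, "normal"), 5L)
  # with the calf-contact bonds removed the normal path is down to 2
  g2 <- g
  g2$bonds <- g2$bonds[!g2$bonds$contact_formed, ]
  expect_equal(count_path_bonds(g2, "normal"), 2L)
  g0 <- g; g0$bonds <- g0$bonds[0, ]
  expect_error(count_path_bonds(g0, "normal"), "empty")
})

test_that("tangential loading unfolds via Separation I4 then I3 with theta 45 -> 75", {
  g <- build_default_integrin()
  tr <- simulate_loading(g, loading_protocol("tangential", force = 70))
  expect_identical(tr$events, c("SeparationI4", "SeparationI3"))
  expect_identical(tr$final_state, "extended")
  expect_equal(tail(tr$theta_series, 1), 75)
  expect_true(all(tr$phi_series == 140))
  # below both barriers nothing separates
  low <- simulate_loading(g, loading_protocol("tangential", force = 50))
  expect_length(low$events, 0)
  expect_identical(low$final_state, "bent")
})

test_that("normal loading rotates, forms contacts and detaches before unfolding", {
  g <- build_default_integrin()
  tr <- simulate_loading(g, loading_protocol("normal", force = 70,
                                             ligand_strength = 70))
  expect_identical(tr$events, c("Rotation", "ContactBondsFormed", "LigandDetach"))
  expect_identical(tr$final_state, "bent")
  expect_equal(tail(tr$phi_series, 1), 100)
  expect_true(all(tr$theta_series == 45))
  # an artificially strong ligand transmits enough force to dissociate the
  # five-bond network
  strong <- simulate_loading(g, loading_protocol("normal", force = 150,
                                                 ligand_strength = 200))
  expect_true("Dissociation" %in% strong$events)
  expect_identical(strong$final_state, "extended")
})

test_that("direction dichotomy holds over a 0-200 pN force sweep", {
  g <- build_default_integrin()
  for (f in seq(0, 200, by = 5)) {
    tt <- simulate_loading(g, loading_protocol("tangential", force = f))
    tn <- simulate_loading(g, loading_protocol("normal", force = f,
                                               ligand_strength = 70))
    if (f >= 60) expect_identical(tt$final_state, "extended")
    expect_identical(tn$final_state, "bent")
    # event-order invariants
    ei4 <- match("SeparationI4", tt$events)
    ei3 <- match("SeparationI3", tt$events)
    if (!is.na(ei3)) expect_lt(ei4, ei3)
    er <- match("Rotation", tn$events)
    ec <- match("ContactBondsFormed", tn$events)
    if (!is.na(ec)) expect_lt(er, ec)
    # extended iff both baseline bonds broke
    expect_identical(tt$final_state == "extended", tt$broken_bond_count >= 2)
    # theta moves only tangentially, phi only normally
    expect_true(all(tn$theta_series == 45))
    expect_true(all(tt$phi_series == 140))
  }
})

test_that("no bond-breaking order lets normal loading unfold with a 70 pN ligand", {
  # exhaustive oracle: the five-bond network dissociates only above 140 pN,
  # but a 70 pN ligand detaches first, so no breaking order can start
  g <- build_default_integrin()
  network_threshold <- g$network_threshold
  ligand <- 70
  bonds <- seq_len(5)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) for (p in perms(v[-i])) out <- c(out, list(c(v[i], p)))
    out
  }
  for (order in perms(bonds)) {
    broken <- logical(5)
    for (b in order) {
      # transmitting enough force to break any network bond requires the
      # collective threshold, which exceeds what the ligand can carry
      force_needed <- network_threshold
      if (ligand < force_needed) break   # ligand detaches: sequence ends
      broken[b] <- TRUE
    }
    baseline_broken <- sum(broken[1:2])  # the two interdomain bonds
    expect_lt(baseline_broken, 2)        # never reaches the extended state
  }
})

test_that("Bell rescaling reproduces the loading-rate force shift", {
  expect_equal(bell_force_scale(39.9, 10, 10, 1.42), 39.9)
  # a million-fold higher loading rate roughly doubles the measured force
  f <- bell_force_scale(39.9, 1, 1e6, 1.42)
  expect_equal(f, 39.9 + (4.114 / 1.42) * log(1e6), tolerance = 1e-12)
  expect_equal(f, 79.9, tolerance = 0.05 / 79.9)
  # monotone in rate
  rates <- 10^(0:6)
  fs <- vapply(rates, function(r) bell_force_scale(39.9, 1, r, 1.42), numeric(1))
  expect_true(all(diff(fs) > 0))
  expect_error(bell_force_scale(39.9, 1, 0, 1.42), "> 0")
})

test_that("emitted curves carry the trace's unfolding signature", {
  g <- build_default_integrin()
  tr <- simulate_loading(g, loading_protocol("tangential", force = 70))
  # zero-noise emission: both separation peaks at exactly 6 pN
  cv <- emit_synthetic_curve(tr, zero_noise_spec(), seed = 2)
  pk <- analyze_curve(cv, noise = known_noise(2))
  expect_equal(nrow(pk), 2L)
  expect_equal(pk$amplitude_pN, c(6, 6), tolerance = 1e-9)

  tn <- simulate_loading(g, loading_protocol("normal", force = 70))
  cvn <- emit_synthetic_curve(tn, zero_noise_spec(), seed = 2)
  expect_equal(nrow(analyze_curve(cvn, noise = known_noise(2))), 0L)

  # a normal trace that never detached is incomplete
  stuck <- simulate_loading(g, loading_protocol("normal", force = 100,
                                                ligand_strength = 200))
  expect_error(emit_synthetic_curve(stuck), "incomplete")
})

test_that("activation signal is linear in the sliding fraction between 20% and 60%", {
  expect_equal(activation_vs_tangential_fraction(0), 20)
  expect_equal(activation_vs_tangential_fraction(1), 60)
  expect_equal(activation_vs_tangential_fraction(0.5), 40)
  expect_error(activation_vs_tangential_fraction(1.2), "<= 1")
})
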