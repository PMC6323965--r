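test_that("epsilon vanishes for translation-like modes and matches the two-bead stretch", {
  # pure translation: all per-residue blocks equal -> differences vanish
  fix <- jittered_chain(5)
  net <- contact_network(fix)
  modes <- normal_modes(build_hessian(net, fix), network = net)
  fake <- modes
  tvec <- rep(c(1, 0, 0) / sqrt(fix$n), fix$n)
  fake$vectors[, which(!modes$rigid)[1]] <- tvec
  eps <- epsilon_parameters(fake, net)
  expect_equal(eps[1, ], rep(0, fix$n), tolerance = 1e-14)

  # two beads in contact, orthonormal stretch mode e = (u, -u) with
  # 2|u|^2 = 1: epsilon per bead = |e_1 - e_2|^2 = 4|u|^2 = 2
  two <- make_structure(rbind(c(0, 0, 0), c(3.8, 0, 0)))
  net2 <- contact_network(two)
  modes2 <- normal_modes(build_hessian(net2, two), network = net2)
  eps2 <- epsilon_parameters(modes2, net2)
  expect_equal(dim(eps2), c(1, 2))
  expect_equal(unname(eps2[1, ]), c(2, 2), tolerance = 1e-12)
})

test_that("epsilon is invariant under uniform spring-constant scaling", {
  fix <- jittered_chain(5)
  e1 <- enm(fix, base_k = 1)
  e2 <- enm(fix, base_k = 2)
  eps1 <- epsilon_parameters(e1$modes, e1$network)
  eps2 <- epsilon_parameters(e2$modes, e2$network)
  expect_equal(eps1, eps2, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("identical parameter sets give exactly zero free energy", {
  fix <- generate_fixture("cubic_cluster", n = 8, jitter = 0.2, seed = 5)
  fit <- enm(fix)
  eps <- epsilon_parameters(fit$modes, fit$network)
  dg <- free_energy_profile(eps, eps)
  expect_identical(as.vector(dg), rep(0, fix$n))
  expect_error(free_energy_profile(eps, eps[-1, , drop = FALSE]),
               "mode-count mismatch")
})

test_that("uniformly stiffened springs produce a null free-energy profile", {
  fix <- jittered_chain(5)
  net1 <- contact_network(fix, base_k = 1)
  net2 <- contact_network(fix, base_k = 2)   # every spring x2
  m1 <- normal_modes(build_hessian(net1, fix), network = net1)
  m2 <- normal_modes(build_hessian(net2, fix), network = net2)
  dg <- free_energy_profile(epsilon_parameters(m1, net1),
                            epsilon_parameters(m2, net1))
  expect_lt(max(abs(dg)), 1e-8)
})

test_that("free energy matches the Gaussian-normalization quadrature oracle", {
  fix <- jittered_chain(4)
  xyz <- unname(fix$xyz)
  springs0 <- oracle_springs(xyz)

  # stiffening the terminal contact (an UP mutation at bead 1)
  fit <- sbsmma(fix, mutation_up(1, alpha = 10))
  dg_oracle <- oracle_delta_g(xyz, springs0, oracle_up_down(springs0, 1, 10))
  expect_equal(fit$delta_g, dg_oracle, tolerance = 1e-6)

  # softening an interior residue
  fit_dn <- sbsmma(fix, mutation_down(3, alpha = 0.1))
  dg_dn <- oracle_delta_g(xyz, springs0, oracle_up_down(springs0, 3, 0.1))
  expect_equal(fit_dn$delta_g, dg_dn, tolerance = 1e-6)
})

test_that("modulation profile removes the chain (or global) mean", {
  expect_equal(modulation_profile(c(5, 5, 5), rep("A", 3)), c(0, 0, 0))
  expect_equal(modulation_profile(c(1, 2, 3), rep("A", 3)), c(-1, 0, 1))
  # two chains, chain-wise vs global centering
  dg <- c(1, 3, 10, 14)
  ch <- c("A", "A", "B", "B")
  expect_equal(modulation_profile(dg, ch), c(-1, 1, -2, 2))
  expect_equal(modulation_profile(dg, ch, scope = "global"), dg - 7)
  set.seed(11)
  r <- rnorm(20)
  chains <- rep(c("A", "B"), each = 10)
  dh <- modulation_profile(r, chains)
  expect_lt(max(abs(tapply(dh, chains, mean))), 1e-10)
})

test_that("site modulation is the member mean, zero for a whole chain", {
  fix <- jittered_chain(6)
  dh <- modulation_profile(seq_len(6), fix$residues$chain)
  expect_equal(site_modulation(dh, fix, fix$labels), 0, tolerance = 1e-10)
  expect_equal(site_modulation(dh, fix, "A:2"), dh[2])
  s <- make_structure(rbind(c(0, 0, 0), c(3.8, 0, 0)))
  expect_equal(site_modulation(c(1, -3), s, c("A:1", "A:2")), -1)
  expect_error(site_modulation(dh, fix, character(0)), "empty site")
})

test_that("modulation range is UP minus DOWN and keeps zero chain mean", {
  fix <- jittered_chain(6)
  up <- sbsmma(fix, mutation_up(3, alpha = 2))
  down <- sbsmma(fix, mutation_down(3, alpha = 0.1))
  rng <- modulation_range(up$delta_h, down$delta_h)
  expect_equal(rng + down$delta_h, up$delta_h, tolerance = 1e-15)
  expect_lt(abs(mean(rng)), 1e-10)
  # same alpha on both sides collapses the range to zero
  same <- modulation_range(up$delta_h, up$delta_h)
  expect_equal(same, rep(0, fix$n))
  expect_error(modulation_range(up$delta_h, down$delta_h[-1]),
               "length mismatch")
})

test_that("extreme-residue flagging splits by threshold into disjoint lists", {
  s <- make_structure(rbind(c(0, 0, 0), c(3.8, 0, 0), c(7.6, 0, 0.5)))
  f <- flag_extreme_residues(c(-2, 0, 2), s, tau = 1, type = "absolute")
  expect_equal(f$high, "A:3")
  expect_equal(f$low, "A:1")
  z <- flag_extreme_residues(rep(0, 3), s)
  expect_length(z$high, 0)
  expect_length(z$low, 0)
  set.seed(13)
  fix <- jittered_chain(20)
  dh <- modulation_profile(rnorm(20), fix$residues$chain)
  for (type in c("sd", "absolute", "quantile")) {
    tau <- if (type == "quantile") 0.2 else 0.8
    fl <- flag_extreme_residues(dh, fix, tau = tau, type = type)
    expect_length(intersect(fl$high, fl$low), 0)
  }
})
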