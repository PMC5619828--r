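test_that("seed_filaments hits the target density with straight chains", {
  cfg <- assembly_config()
  net <- seed_filaments(rep(10, 3), cfg, seed = 4)
  n <- nrow(net$positions)
  expect_lt(abs(n / (3.5 * 1000) - 1), 0.05) # 3500 +- 5%
  # every chain spans the filament length
  ee <- vapply(net$chains, function(ch) {
    sqrt(sum((net$positions[ch[length(ch)], ] - net$positions[ch[1], ])^2))
  }, numeric(1))
  expect_true(all(abs(ee - 4.0) < 1e-9))
  # determinism
  net2 <- seed_filaments(rep(10, 3), cfg, seed = 4)
  expect_identical(net$positions, net2$positions)
  expect_error(seed_filaments(rep(3, 3), cfg), "configuration")
})

test_that("polymerization keeps total filament length approximately constant", {
  cfg <- assembly_config()
  net <- seed_filaments(rep(6, 3), cfg, seed = 5)
  expect_identical(polymerize(net, 0, cfg), net) # zero steps: identity
  n0 <- nrow(net$positions)
  net2 <- polymerize(net, 2000, cfg, seed = 5)
  expect_lt(abs(nrow(net2$positions) / n0 - 1), 0.05)
  trace <- attr(net2, "count_trace")
  expect_true(all(abs(trace / n0 - 1) < 0.05))
})

test_that("a lone filament with no neighbours gains no particles", {
  cfg <- assembly_config()
  net <- seed_filaments(rep(20, 3), cfg, seed = 6)
  # keep a single chain
  ch <- net$chains[[1]]
  lone <- filament_network(net$positions[ch, , drop = FALSE],
                           list(seq_along(ch)), box = rep(20, 3))
  lone <- dpdcell:::rebuild_chain_topology(lone, cfg)
  out <- polymerize(lone, 1000, cfg, seed = 7)
  expect_lte(nrow(out$positions), nrow(lone$positions))
})

test_that("cross-link formation respects its binding constraints", {
  net <- network_box()
  cl <- net$bonds[net$bonds$class == "crosslink", ]
  expect_gt(nrow(cl), 0)
  chain_id <- dpdcell:::chain_id_of(net)
  # every merged CL joins two distinct filaments
  expect_true(all(chain_id[cl$i] != chain_id[cl$j]))
  # at most one CL per filament particle
  expect_false(anyDuplicated(c(cl$i, cl$j)) > 0)
  # free-CL count trace is recorded and reaches a low plateau
  tr <- attr(net, "free_cl_trace")
  expect_gt(length(tr), 0)
  expect_lte(tail(tr, 1), min(tr))
})

test_that("zero CL density yields a filament gas", {
  cfg <- assembly_config(n_cl = 0)
  net <- seed_filaments(rep(5, 3), cfg, seed = 8)
  out <- form_crosslinks(net, cfg, seed = 8)
  expect_equal(sum(out$bonds$class == "crosslink"), 0)
})

test_that("mean CLs per filament increases with CL density", {
  base <- assembly_config(polymerize_steps = 0, cl_max_steps = 1.2e4,
                          window = 4000)
  means <- vapply(c(0.3, 0.9), function(ncl) {
    cfg <- base
    cfg$n_cl <- ncl
    m <- vapply(1:2, function(s) {
      net <- assemble_network(rep(5, 3), cfg, seed = 20 + s)
      topology_stats(net)$cl_per_filament_mean
    }, numeric(1))
    mean(m)
  }, numeric(1))
  expect_gt(means[2], means[1])
})

test_that("assembly statistics are reproducible for a fixed seed", {
  cfg <- assembly_config(polymerize_steps = 500, cl_max_steps = 4000,
                         window = 2000)
  a <- assemble_network(rep(5, 3), cfg, seed = 31)
  b <- assemble_network(rep(5, 3), cfg, seed = 31)
  expect_identical(a$positions, b$positions)
  expect_identical(a$bonds, b$bonds)
})

test_that("carving retains only particles inside the cell volume", {
  cfg <- assembly_config(polymerize_steps = 0, cl_max_steps = 4000,
                         window = 2000)
  net <- assemble_network(rep(8, 3), cfg, seed = 9)
  outer <- membrane_mesh() # 6 um sphere at the origin
  carved <- dpdcell:::carve_network(net, outer, NULL)
  inside <- dpdcell:::cpp_points_in_mesh(carved$positions, outer$positions,
                                         outer$tris)
  expect_true(all(inside)) # 100% post-carve containment
  expect_true(all(lengths(carved$chains) >= 2))
})

test_that("the assembled mini cell satisfies the link constraints", {
  b <- mini_cell()
  net <- b$network
  expect_silent(validate_network(net)) # includes one-link-per-particle
  expect_gt(nrow(net$links), 0)
  expect_false(anyDuplicated(net$links$particle) > 0)
  st <- b$stats
  expect_true(st$cell_linked_fraction >= 0 && st$cell_linked_fraction <= 1)
  expect_true(st$nucleus_linked_fraction >= 0 &&
                st$nucleus_linked_fraction <= 1)
  # torsion quadruples carry their constructed equilibrium angles
  if (nrow(net$torsions)) {
    expect_true(all(is.finite(net$torsions$phi0)))
    expect_equal(unique(net$torsions$ktor), b$config$k_tor)
  }
})
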