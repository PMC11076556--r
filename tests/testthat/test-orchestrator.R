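test_that("ring rotation is a cyclic bijection with inverse and period", {
  ring <- c("A", "B", "C")
  pk <- lapply(ring, function(id) list(tensors = id, origin_client = id))
  cw <- rotate_shared_layers(ring, pk, "clockwise")
  # A's packet moves to B, B's to C, C's to A
  expect_equal(cw[[1]]$origin_client, "C")
  expect_equal(cw[[2]]$origin_client, "A")
  expect_equal(cw[[3]]$origin_client, "B")
  # |ring| clockwise applications = identity
  r3 <- pk
  for (i in 1:3) r3 <- rotate_shared_layers(ring, r3, "clockwise")
  expect_identical(r3, pk)
  # clockwise then anticlockwise = identity
  expect_identical(rotate_shared_layers(ring, cw, "anticlockwise"), pk)
  # bijection: every packet still present exactly once
  expect_setequal(vapply(cw, `[[`, "", "origin_client"), ring)
  # singleton ring is the identity
  expect_identical(rotate_shared_layers("A", pk[1], "clockwise"), pk[1])
  expect_error(rotate_shared_layers(ring, pk[1:2], "clockwise"), "mismatch")
})

test_that("orbit formation recovers planted clusters and handles degeneracy", {
  # degenerate: identical features -> one orbit
  f0 <- matrix(1, nrow = 6, ncol = 3)
  fo <- form_orbits(f0, kmax = 5, seed = 1)
  expect_equal(fo$k, 1L)
  expect_equal(fo$assignment, rep(1L, 6))
  # three well-separated planted clusters
  set.seed(2)
  f <- rbind(matrix(rnorm(6, 0, 0.1), 2, 3),
             matrix(rnorm(6, 5, 0.1), 2, 3) + 5,
             matrix(rnorm(6, 20, 0.1), 2, 3))
  fo <- form_orbits(f, kmax = 5, seed = 3)
  expect_equal(fo$k, 3L)
  expect_equal(length(unique(fo$assignment[1:2])), 1)
  expect_equal(length(unique(fo$assignment[3:4])), 1)
  expect_equal(length(unique(fo$assignment[5:6])), 1)
  expect_equal(length(unique(fo$assignment)), 3)
})

test_that("initiation orders orbits by decreasing mean weight similarity", {
  cfg <- tiny_config()
  sc <- generate_scenario(cfg)
  net <- build_network(sc$clients, sc$benchmark, seed = 7,
                       recipe = tiny_recipe(), n_init = 2L,
                       ae_epochs = 10L, probe_size = 10L, kmax = 2L)
  net <- initiate(net)
  means <- vapply(net$orbit_config$orbits, function(r)
    mean(vapply(as.character(r), function(k) net$clients[[k]]$weight_rho,
                numeric(1))), numeric(1))
  expect_true(all(diff(means) <= 1e-12))
  # every client holds exactly one packet; orbits partition the client set
  expect_setequal(unlist(net$orbit_config$orbits), 1:cfg$n_clients)
  for (cl in net$clients) expect_false(is.null(cl$packet))
})

test_that("maintenance keeps orbits a partition and logs deterministically", {
  cfg <- tiny_config()
  sc <- generate_scenario(cfg)
  run_once <- function() {
    net <- build_network(sc$clients, sc$benchmark, seed = 7,
                         recipe = tiny_recipe(), n_init = 2L,
                         ae_epochs = 10L, probe_size = 10L, kmax = 2L)
    run_protocol(net, 5L)
  }
  n1 <- run_once(); n2 <- run_once()
  expect_identical(n1$events, n2$events)
  expect_identical(n1$orbit_history, n2$orbit_history)
  expect_identical(flatten_params(n1$clients[["1"]]$model),
                   flatten_params(n2$clients[["1"]]$model))
  # at every recorded melioration the orbits partition the client set
  for (m in unique(n1$orbit_history$melioration_index)) {
    oh <- n1$orbit_history[n1$orbit_history$melioration_index == m, ]
    expect_setequal(oh$client_id, 1:cfg$n_clients)
    expect_equal(anyDuplicated(oh$client_id), 0)
  }
  expect_equal(min(vapply(n1$clients, function(cl) cl$meliorations, integer(1))), 5)
})

test_that("inter-orbit access is inner-to-outer only with provenance", {
  cfg <- tiny_config()
  sc <- generate_scenario(cfg)
  net <- build_network(sc$clients, sc$benchmark, seed = 7,
                       recipe = tiny_recipe(), n_init = 2L,
                       ae_epochs = 10L, probe_size = 10L, kmax = 2L)
  net <- initiate(net)
  # force a known two-orbit configuration
  net$orbit_config$orbits <- list(c(1L, 2L), 3L)
  pkt <- pull_inner_orbit_layers(net, 3L)
  expect_lt(pkt$origin_orbit, orbit_of(net, 3L))
  expect_true(pkt$origin_client %in% c(1L, 2L))
  expect_error(pull_inner_orbit_layers(net, 1L), "access denied")
})

test_that("per-orbit clock barriers confine slow clients to their own orbit", {
  cfg <- tiny_config(n_clients = 4L, samples_per_client = 40L)
  sc <- generate_scenario(cfg)
  slow_fn <- function(client_id, melioration_index) {
    if (client_id == 3L && melioration_index >= 3) 3 else 1
  }
  # a wide threshold freezes the orbit structure (no removals, and no
  # singleton orbits exist so no rejoins), leaving only clock mechanics
  net <- build_network(sc$clients, sc$benchmark, seed = 7,
                       recipe = tiny_recipe(), n_init = 2L, threshold = 10,
                       ae_epochs = 10L, probe_size = 10L, kmax = 2L,
                       duration_fn = slow_fn)
  net <- initiate(net)
  net$orbit_config$orbits <- list(c(1L, 2L), c(3L, 4L))
  for (i in 1:3) net <- maintenance_round(net)
  membership <- lapply(net$orbit_config$orbits, sort)
  expect_equal(length(membership), 2)
  expect_true(any(vapply(membership, identical, logical(1), c(1L, 2L))))
  expect_true(any(vapply(membership, identical, logical(1), c(3L, 4L))))
  # orbit barrier: ring members share the slow member's clock
  expect_equal(net$clients[["3"]]$clock, net$clients[["4"]]$clock)
  expect_equal(net$clients[["1"]]$clock, net$clients[["2"]]$clock)
  # the unaffected orbit finishes earlier on the simulated clock
  expect_lt(net$clients[["1"]]$clock, net$clients[["3"]]$clock)
})

test_that("a perfectly symmetric micro-network never regroups", {
  cfg <- tiny_config()
  sc <- generate_scenario(cfg)
  base <- sc$clients[[1]]
  clients <- lapply(1:3, function(k) { d <- base; d$client_id <- k; d })
  net <- build_network(clients, sc$benchmark, seed = 11,
                       recipe = tiny_recipe(), n_init = 2L,
                       ae_epochs = 10L, probe_size = 10L, kmax = 2L,
                       identical_client_seeds = TRUE)
  net <- run_protocol(net, 6L)
  expect_equal(nrow(regroup_events(net)), 0)
  rhos <- vapply(net$clients, function(cl) cl$weight_rho, numeric(1))
  expect_lt(max(rhos) - min(rhos), 1e-12)
})
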