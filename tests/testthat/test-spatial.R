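test_that("cluster detection needs a fully surrounded seed", {
  l <- chip_layout("t", 1, 1, 1, 15, 15)
  g <- nominal_positions(l)
  graph <- build_neighbour_graph(g)
  # scattered singletons: no bead has six non-decoded neighbours
  decoded <- rep(TRUE, nrow(g))
  decoded[c(5, 40, 90, 130, 200)] <- FALSE
  expect_length(find_nondecoded_clusters(graph, decoded, min_size = 3), 0L)
})

test_that("injected discs are recovered exactly, separately per disc", {
  sec <- make_section(seed = 51, n_rows = 35, n_cols = 35,
                      non_decode_rate = 0)
  graph <- sec$graph
  d1 <- hexbead:::grow_disc(graph, 35 * 8 + 8, 60)
  d2 <- hexbead:::grow_disc(graph, 35 * 26 + 26, 60)
  decoded <- rep(TRUE, graph$n)
  decoded[c(d1, d2)] <- FALSE
  cl <- find_nondecoded_clusters(graph, decoded)
  expect_length(cl, 2L)
  found <- lapply(cl, `[[`, "members")
  expect_true(setequal(found[[1]], d1) || setequal(found[[1]], d2))
  expect_setequal(unlist(found), c(d1, d2))
})

test_that("cluster detection agrees with a connected-components oracle", {
  skip_if_not_installed("igraph")
  set.seed(3)
  l <- chip_layout("t", 1, 1, 1, 20, 20)
  g <- nominal_positions(l)
  graph <- build_neighbour_graph(g)
  for (k in 1:15) {
    decoded <- runif(graph$n) > runif(1, 0.2, 0.6)
    cl <- find_nondecoded_clusters(graph, decoded, min_size = 10)
    # oracle: components of the non-decoded subgraph that contain a seed
    nd <- !decoded
    e_nd <- graph$edges[nd[graph$edges[, 1]] & nd[graph$edges[, 2]], ,
                        drop = FALSE]
    ig <- igraph::make_empty_graph(graph$n, directed = FALSE)
    ig <- igraph::add_edges(ig, t(e_nd))
    memb <- igraph::components(ig)$membership
    seeds <- which(nd & graph_degree(graph) == 6 &
                   vapply(graph$adj, function(a) all(nd[a]), logical(1)))
    oracle <- Filter(function(m) length(m) >= 10 && any(m %in% seeds),
                     split(which(nd), memb[nd]))
    expect_setequal(lapply(cl, `[[`, "members"),
                    lapply(unname(oracle), as.integer))
  }
})

test_that("halo expansion is ring-monotone and matches brute force", {
  sec <- make_section(seed = 52, n_rows = 20, n_cols = 20,
                      non_decode_rate = 0)
  graph <- sec$graph
  disc <- hexbead:::grow_disc(graph, 20 * 10 + 10, 7)  # hex flower
  decoded <- rep(TRUE, graph$n)
  decoded[disc] <- FALSE
  cl <- find_nondecoded_clusters(graph, decoded, min_size = 7)
  expect_length(cl, 1L)
  h0 <- expand_cluster(cl, graph, decoded, rings = 0)[[1]]
  h1 <- expand_cluster(cl, graph, decoded, rings = 1)[[1]]
  h2 <- expand_cluster(cl, graph, decoded, rings = 2)[[1]]
  expect_length(h0, 0L)
  expect_true(all(h1 %in% h2))
  # brute force ring 1: decoded beads sharing an edge with a member
  e <- graph$edges
  touch <- unique(c(e[e[, 1] %in% disc, 2], e[e[, 2] %in% disc, 1]))
  expect_setequal(h1, setdiff(touch, disc))
})

test_that("bright features are filtered by mass and circularity", {
  blank <- matrix(400, 50, 50)
  expect_equal(nrow(detect_bright_features(blank, threshold = 1000)), 0L)

  sec <- make_section(seed = 5, n_rows = 25, n_cols = 25,
                      non_decode_rate = 0,
                      artifacts = list(artifact_spec("bright_bead",
                                                     bead = 312L)))
  ft <- detect_bright_features(sec$image,
                               bead_centres = sec$beads[, c("x", "y")])
  expect_equal(nrow(ft), 1L)
  expect_gte(ft$mass, 40)
  expect_equal(ft$bead, 312L)
  expect_lt(abs(ft$cx - sec$beads$x[312]), 1)
  expect_lt(abs(ft$cy - sec$beads$y[312]), 1)

  # an elongated bright streak has low circularity and is rejected
  bar <- matrix(400, 60, 60)
  bar[20:22, 10:39] <- 50000
  expect_equal(nrow(detect_bright_features(bar, threshold = 10000,
                                           min_mass = 40)), 0L)
  kept <- detect_bright_features(bar, threshold = 10000, min_mass = 40,
                                 min_circularity = 0)
  expect_equal(kept$mass, 90L)
})

test_that("bright beads flag themselves and their six neighbours", {
  sec <- make_section(seed = 5, n_rows = 25, n_cols = 25,
                      non_decode_rate = 0,
                      artifacts = list(artifact_spec("bright_bead",
                                                     bead = 312L)))
  ft <- detect_bright_features(sec$image,
                               bead_centres = sec$beads[, c("x", "y")])
  m <- flag_bright_neighbours(ft, sec$graph)
  expect_setequal(masked_beads(m, "bright_bead"), 312L)
  expect_setequal(masked_beads(m, "bright_neighbour"),
                  sec$graph$adj[[312]])
  expect_length(masked_beads(m, "bright_neighbour"), 6L)
  expect_equal(nrow(flag_bright_neighbours(ft[0, ], sec$graph)), 0L)
})

test_that("neighbours overlapped by a bright spot show inflated signal", {
  sec <- make_section(seed = 61, n_rows = 20, n_cols = 20,
                      n_bead_types = 10, non_decode_rate = 0,
                      artifacts = list(artifact_spec("bright_bead",
                                                     bead = 210L,
                                                     radius_factor = 2.3)))
  e <- extract_all(sec$image, sec$beads)
  res <- residual_log_intensity(data.frame(
    bead_type_id = sec$beads$bead_type_id, intensity = e$intensity))
  nb <- sec$graph$adj[[210]]
  # at least half the neighbours at >= 2x their type median (residual >= 1)
  expect_gte(sum(res[nb] >= 1, na.rm = TRUE), 3)
})

test_that("low-pixel detection keys off the modal background", {
  set.seed(8)
  img <- matrix(rnorm(10000, 500, 10), 100, 100)
  expect_equal(nrow(detect_low_pixels(img)), 0L)
  img[41, 61] <- 5
  lp <- detect_low_pixels(img)
  expect_equal(nrow(lp), 1L)
  expect_equal(c(lp$x, lp$y), c(60, 40))  # 0-based coordinates
  # threshold monotonicity
  img[10, 10] <- 200
  n_50 <- nrow(detect_low_pixels(img, low_fraction = 0.5))
  n_30 <- nrow(detect_low_pixels(img, low_fraction = 0.3))
  expect_gte(n_50, n_30)
})

test_that("beads whose background window covers a low pixel are flagged", {
  sec <- make_section(seed = 71, n_rows = 20, n_cols = 20,
                      non_decode_rate = 0,
                      artifacts = list(artifact_spec("low_pixel",
                                                     near_bead = 210L,
                                                     value = 5)))
  px <- sec$truth[[1]]$pixels
  lp <- detect_low_pixels(sec$image)
  expect_true(any(lp$x == px$x & lp$y == px$y))
  m <- flag_low_pixel_beads(lp[lp$x == px$x & lp$y == px$y, ],
                            sec$beads, sec$image)
  flagged <- masked_beads(m)
  # exactly the beads whose 17x17 windows cover the pixel; at most 12
  covers <- which(abs(floor(sec$beads$x) - px$x) <= 8 &
                  abs(floor(sec$beads$y) - px$y) <= 8)
  expect_setequal(flagged, covers)
  expect_lte(length(flagged), 12L)
  # the corrupted mean5 background sits below the robust median5
  for (i in flagged) {
    ctr <- c(sec$beads$x[i], sec$beads$y[i])
    expect_lt(compute_background(sec$image, ctr),
              compute_background(sec$image, ctr,
                extraction_options(background_rule = "median5")))
  }
  far <- data.frame(x = 5, y = 5, value = 5)
  expect_equal(nrow(flag_low_pixel_beads(far, sec$beads[300, ],
                                         sec$image)), 0L)
})

test_that("twin pairs count edges with shared identities, once each", {
  l <- chip_layout("t", 1, 1, 1, 10, 10)
  graph <- build_neighbour_graph(nominal_positions(l))
  expect_equal(count_twin_pairs(graph, seq_len(graph$n)), 0L)
  expect_equal(count_twin_pairs(graph, rep(1L, graph$n)),
               nrow(graph$edges))
  # hex flower: centre + one petal share a type -> exactly one pair
  l7 <- chip_layout("t", 1, 1, 1, 3, 3)
  g7 <- nominal_positions(l7)
  gr7 <- build_neighbour_graph(g7)
  ctr <- which(g7$g_row == 1 & g7$g_col == 1)
  ids <- seq_len(9) + 100L
  ids[gr7$adj[[ctr]][1]] <- ids[ctr]
  expect_equal(count_twin_pairs(gr7, ids), 1L)
  # brute-force double loop oracle on a random assignment
  set.seed(2)
  ids <- sample(c(-1L, 1:7), graph$n, replace = TRUE)
  brute <- sum(apply(graph$edges, 1, function(e)
    ids[e[1]] >= 0 && ids[e[1]] == ids[e[2]]))
  expect_equal(count_twin_pairs(graph, ids), brute)
})

test_that("idealized twin expectation reproduces the printed value", {
  expect_identical(expected_twin_pairs(1e6, 6, 50000), 60)
  expect_equal(expected_twin_pairs(1000, 4, 1), 2000)
  expect_error(expected_twin_pairs(10, 6, 0), "n_types")
})

test_that("the permutation null is calibrated and seed-stable", {
  sec <- make_section(seed = 81, n_rows = 20, n_cols = 20,
                      n_bead_types = 25)
  ids <- sec$beads$bead_type_id
  p1 <- permutation_null_twins(sec$graph, ids, n_perm = 99, seed = 5)
  p2 <- permutation_null_twins(sec$graph, ids, n_perm = 99, seed = 5)
  expect_identical(p1, p2)
  # permutations preserve the decoded ID multiset: null values match a
  # recount under any permutation, and random ids give unremarkable p
  expect_gt(p1$p_value, 0.01)

  # construct a strong twin excess by ID swaps, which leave the type
  # multiset (and hence the permutation null) untouched: move one
  # replicate of a type next to another by swapping identities
  ids2 <- ids
  made <- 0L
  for (i in seq_along(ids2)) {
    if (made >= 40L) break
    t <- ids2[i]
    if (t < 0) next
    nb <- sec$graph$adj[[i]]
    u <- nb[ids2[nb] >= 0 & ids2[nb] != t][1]
    j <- which(ids2 == t & seq_along(ids2) != i & !(seq_along(ids2) %in% nb))[1]
    if (is.na(u) || is.na(j)) next
    tmp <- ids2[u]; ids2[u] <- ids2[j]; ids2[j] <- tmp
    made <- made + 1L
  }
  expect_equal(sort(ids2), sort(ids))
  p3 <- permutation_null_twins(sec$graph, ids2, n_perm = 200, seed = 5)
  expect_lte(p3$p_value, 0.01)
})

test_that("permutation null mean matches the fixed-multiset expectation", {
  sec <- make_section(seed = 91, n_rows = 25, n_cols = 25,
                      n_bead_types = 30, non_decode_rate = 0)
  ids <- sec$beads$bead_type_id
  pn <- permutation_null_twins(sec$graph, ids, n_perm = 400, seed = 2)
  n <- length(ids)
  nt <- table(ids)
  expectation <- nrow(sec$graph$edges) *
    sum(nt * (nt - 1)) / (n * (n - 1))
  se <- sd(pn$null) / sqrt(length(pn$null))
  expect_lt(abs(mean(pn$null) - expectation), 3 * se)
})

test_that("fractional intensity maps localize and expose trends", {
  beads <- data.frame(x = 10.5 + 0:99 * 6, y = 20.5, intensity = 1000,
                      bead_type_id = 1L)
  m <- fractional_intensity_map(beads, bins = 10)
  expect_equal(sum(!is.na(m)), 1L)
  expect_equal(m[6, 6], log2(1000))

  # injected monotone dependence on frac_x is recovered across bins
  set.seed(4)
  n <- 20000
  fx <- runif(n)
  beads2 <- data.frame(x = floor(runif(n, 10, 200)) + fx,
                       y = runif(n, 10, 200),
                       intensity = 1000 * (1 + 0.3 * fx) *
                         exp(rnorm(n, 0, 0.02)),
                       bead_type_id = 1L)
  m2 <- fractional_intensity_map(beads2, bins = 5)
  col_means <- colMeans(m2, na.rm = TRUE)
  expect_true(all(diff(col_means) > 0))

  # location-independent intensities: bin means stay near the grand mean
  beads3 <- beads2
  beads3$intensity <- 1000 * exp(rnorm(n, 0, 0.02))
  m3 <- fractional_intensity_map(beads3, bins = 5)
  expect_lt(max(abs(m3 - mean(m3))), 5 * 0.02 / log(2) / sqrt(n / 25))
})
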