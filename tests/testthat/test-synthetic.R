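test_that("type assignment is seeded, uniform, and honours the sentinel", {
  cfg <- simulation_config(seed = 4, n_rows = 10, n_cols = 10,
                           n_bead_types = 5, non_decode_rate = 0.1)
  grid <- nominal_positions(sec_layout <- chip_layout("t", 1, 1, 1, 10, 10),
                            origin = c(12, 12))
  a <- assign_bead_types(grid, cfg)
  b <- assign_bead_types(grid, cfg)
  expect_identical(a, b)
  expect_true(all(a$bead_type_id %in% c(-1L, 1:5)))
  expect_true(any(a$bead_type_id == -1L))
  expect_equal(a$true_intensity, 2^a$true_log2)
})

test_that("single-type assignment makes every edge a twin pair", {
  sec <- make_section(seed = 2, n_rows = 8, n_cols = 8, n_bead_types = 1,
                      non_decode_rate = 0)
  expect_equal(count_twin_pairs(sec$graph, sec$beads$bead_type_id),
               nrow(sec$graph$edges))
})

test_that("same-type pair frequency matches the uniform-type expectation", {
  l <- chip_layout("t", 1, 1, 1, 20, 20)
  grid <- nominal_positions(l, origin = c(12, 12))
  graph <- build_neighbour_graph(grid)
  n_types <- 20L
  counts <- vapply(1:150, function(s) {
    cfg <- simulation_config(seed = s, n_rows = 20, n_cols = 20,
                             n_bead_types = n_types, non_decode_rate = 0)
    count_twin_pairs(graph, assign_bead_types(grid, cfg)$bead_type_id)
  }, integer(1))
  expected <- nrow(graph$edges) / n_types
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("rendering is background plus linear bead flux", {
  cfg <- simulation_config(seed = 3, background_level = 400,
                           background_sd = 10)
  empty <- data.frame(x = numeric(), y = numeric(),
                      true_intensity = numeric())
  img <- render_section_image(empty, cfg, dims = c(60, 60))
  se <- cfg$background_sd / sqrt(length(img))
  expect_lt(abs(mean(img) - cfg$background_level), 3 * se + 0.5)

  one <- data.frame(x = 30.4, y = 29.7, true_intensity = 2000)
  clean <- render_section_image(one, cfg, dims = c(60, 60), noise = FALSE)
  flux <- sum(clean - cfg$background_level)
  expect_lt(abs(flux - 2000 * 2 / 3 * pi * cfg$bead_radius^2) /
            (2000 * 2 / 3 * pi * cfg$bead_radius^2), 0.01)

  two <- data.frame(x = c(20.2, 45.8), y = c(20.1, 44.3),
                    true_intensity = c(1500, 800))
  both <- render_section_image(two, cfg, dims = c(70, 70), noise = FALSE)
  a <- render_section_image(two[1, ], cfg, dims = c(70, 70), noise = FALSE)
  b <- render_section_image(two[2, ], cfg, dims = c(70, 70), noise = FALSE)
  expect_lte(max(abs((a + b - cfg$background_level) - both)), 2)
  expect_error(render_section_image(data.frame(x = 1, y = 1,
                                               true_intensity = 10),
                                    cfg, dims = c(60, 60)), "edge")
})

test_that("artefact injection records complete and correct truth", {
  # empty spec list is the identity
  sec <- make_section(seed = 6, n_rows = 12, n_cols = 12)
  ident <- inject_artifacts(sec$image, sec$beads, list(),
                            graph = sec$graph, config = sec$cfg)
  expect_identical(ident$image, sec$image)
  expect_identical(ident$beads, sec$beads)

  # cluster: >= 80 connected non-decoded beads, one with 6 nd neighbours
  sec <- make_section(seed = 6, n_rows = 25, n_cols = 25,
                      artifacts = list(artifact_spec("nondecoded_cluster",
                                                     size = 80)))
  tr <- sec$truth[[1]]
  expect_gte(length(tr$members), 80L)
  expect_true(all(sec$beads$bead_type_id[tr$members] == -1L))
  nd <- sec$beads$bead_type_id < 0
  has_seed <- any(vapply(tr$members, function(i) {
    a <- sec$graph$adj[[i]]
    length(a) == 6L && all(nd[a])
  }, logical(1)))
  expect_true(has_seed)
  # members form one connected component (flood fill from one member)
  reach <- hexbead:::flood_fill(sec$graph, tr$members[1], nd)
  expect_true(all(tr$members %in% reach))

  # segment shift: every recorded ID matches the bead 6 rows away
  sec <- make_section(seed = 8, n_rows = 20, n_cols = 20,
                      non_decode_rate = 0,
                      artifacts = list(artifact_spec("segment_shift",
                                                     shift = c(0, 6))))
  tr <- sec$truth[[1]]
  rec <- grid_matrix(sec$beads, "bead_type_id", 20, 20)
  true_ids <- matrix(tr$true_ids, 20, 20, byrow = TRUE)
  expect_equal(rec[7:20, ], true_ids[1:14, ])
  expect_true(all(rec[1:6, ] == -1L))

  # conflicting specs error
  expect_error(make_section(seed = 6, n_rows = 25, n_cols = 25,
    artifacts = list(
      artifact_spec("nondecoded_cluster", centre = 313L, size = 60),
      artifact_spec("bright_bead", bead = 313L))), "conflicting")
})

test_that("within-type log2 spread of extracted intensities matches config", {
  sec <- make_section(seed = 31, n_rows = 72, n_cols = 72,
                      n_bead_types = 120, non_decode_rate = 0)
  e <- extract_all(sec$image, sec$beads)
  ok <- !is.na(e$intensity) & e$intensity > 0
  lv <- log2(e$intensity[ok])
  ids <- sec$beads$bead_type_id[ok]
  pooled_var <- tapply(seq_along(lv), ids, function(ix)
    if (length(ix) > 1) c(var(lv[ix]) * (length(ix) - 1), length(ix) - 1)
    else c(0, 0))
  num <- sum(vapply(pooled_var, `[`, numeric(1), 1))
  den <- sum(vapply(pooled_var, `[`, numeric(1), 2))
  pooled_sd <- sqrt(num / den)
  expect_lt(abs(pooled_sd - sec$cfg$log2_within_sd) /
            sec$cfg$log2_within_sd, 0.15)
})

test_that("beads deviating far from their type median are all in truth", {
  sec <- make_section(seed = 13, n_rows = 25, n_cols = 25,
                      n_bead_types = 40, non_decode_rate = 0,
                      artifacts = list(
                        artifact_spec("nondecoded_cluster", size = 60,
                                      halo_factor = 8),
                        artifact_spec("bright_bead", bead = 5L,
                                      peak = 50000)))
  listed <- sort(unique(c(sec$truth[[1]]$members, sec$truth[[1]]$halo,
                          sec$truth[[2]]$bead)))
  res <- residual_log_intensity(data.frame(
    bead_type_id = sec$beads$bead_type_id,
    intensity = sec$beads$true_intensity))
  big <- which(abs(res) > 5 * sec$cfg$log2_within_sd)
  expect_true(all(big %in% listed))
})

test_that("identical config and seed give byte-identical bead-level text", {
  cfg <- simulation_config(seed = 99, n_rows = 12, n_cols = 12,
                           artifacts = list(artifact_spec("bead_jitter",
                                                          n = 3)))
  d1 <- tempfile(); d2 <- tempfile()
  generate_dataset(cfg, d1)
  generate_dataset(cfg, d2)
  expect_identical(readLines(file.path(d1, "beads.txt")),
                   readLines(file.path(d2, "beads.txt")))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("generated datasets round-trip through the readers", {
  cfg <- simulation_config(seed = 55, n_rows = 15, n_cols = 15,
                           artifacts = list(
                             artifact_spec("channel_shift_gradient")))
  dir <- tempfile()
  man <- generate_dataset(cfg, dir)
  expect_true(all(file.exists(unlist(man$paths))))
  img <- read_section_tiff(man$paths$image)
  expect_equal(img, man$image, ignore_attr = TRUE)
  locs <- read_locs(man$paths$locs, expected_count = 225L)
  expect_equal(locs[, "x"], man$beads$x, tolerance = 1e-6)
  bl <- read_beadlevel(man$paths$beadlevel)
  expect_equal(nrow(bl), sum(man$beads$bead_type_id >= 0))
  lay <- read_layout_json(man$paths$layout)
  expect_equal(beads_per_segment(lay), 225L)
  # two-channel config wrote a red image with identical dimensions
  img_red <- read_section_tiff(man$paths$image_red)
  expect_equal(dim(img_red), dim(img))
  unlink(dir, recursive = TRUE)
})
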