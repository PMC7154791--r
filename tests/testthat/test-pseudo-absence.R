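# A toy stack with controlled temperature structure and enough presence
# cells for profiling.
toy_profile_world <- function() {
  g <- grid_spec(40, 40)
  set.seed(31)
  tempv <- matrix(runif(1600, 0, 16), 40, 40)
  depthv <- matrix(runif(1600, 100, 2000), 40, 40)
  st <- layer_stack(list(depth = layer(depthv, g, "depth"),
                         temp = layer(tempv, g, "temp")))
  # presences confined to temp in [4, 6]
  cold <- which(tempv >= 4 & tempv <= 6)
  pres <- structure(list(species = "sp", cells = sort(cold[1:60]),
                         n_cells = 60,
                         provenance = rep("institutional", 60)),
                    class = "bn_presences")
  list(grid = g, stack = st, presences = pres, tempv = tempv)
}

test_that("include-mode profiling keeps the presence envelope, exclude-mode its complement", {
  tw <- toy_profile_world()
  inc <- env_profile_mask(tw$presences, tw$stack, vars = "temp",
                          mode = "include")
  # warm cells are outside a [4,6]-degree presence envelope
  warm <- which(tw$tempv > 14.9)
  expect_false(any(inc$eligible[warm]))
  # presence environments are covered in full
  expect_true(all(inc$eligible[tw$presences$cells]))

  exc <- env_profile_mask(tw$presences, tw$stack, vars = "temp",
                          mode = "exclude")
  expect_true(all(exc$eligible[warm]))
  mid <- which(tw$tempv > 4.5 & tw$tempv < 5.5)
  expect_false(any(exc$eligible[mid]))

  # determinism: same input, same mask
  expect_identical(env_profile_mask(tw$presences, tw$stack)$eligible,
                   env_profile_mask(tw$presences, tw$stack)$eligible)

  few <- tw$presences; few$cells <- few$cells[1:5]; few$n_cells <- 5
  expect_error(env_profile_mask(few, tw$stack), "at least 20")
})

test_that("presences spanning the full range leave almost nothing to exclude", {
  tw <- toy_profile_world()
  all_cells <- seq_len(1600)
  pres_all <- structure(list(species = "sp", cells = all_cells,
                             n_cells = 1600,
                             provenance = rep("OBIS", 1600)),
                        class = "bn_presences")
  inc <- env_profile_mask(pres_all, tw$stack, vars = "temp",
                          mode = "include")
  expect_gt(mean(inc$eligible), 0.99) # mask ~ ocean mask
})

test_that("background sampling honours the 6-km buffer exhaustively", {
  tw <- toy_profile_world()
  mask <- env_profile_mask(tw$presences, tw$stack, vars = "temp",
                           mode = "exclude")
  bg <- sample_background(mask, tw$presences, n = 200, buffer_m = 6000,
                          seed = 3)
  expect_length(bg, 200)
  pxy <- bathyniche:::cell_xy(tw$grid, tw$presences$cells)
  bxy <- bathyniche:::cell_xy(tw$grid, bg)
  dmin <- apply(sqrt(outer(bxy$x, pxy$x, "-")^2 +
                       outer(bxy$y, pxy$y, "-")^2), 1, min)
  expect_true(all(dmin > 6000))
  # on a 3-km grid the buffer excludes the presence cell and the ring of
  # neighbours within 2 cells
  expect_true(all(dmin > 2 * 3000 * sqrt(2) - 3000)) # no adjacent cells

  # n = full eligible set returns everything; seeds reproduce
  pool <- sample_background(mask, tw$presences, n = NULL)
  expect_setequal(sample_background(mask, tw$presences, n = length(pool)),
                  pool)
  s1 <- sample_background(mask, tw$presences, n = 100, seed = 5)
  expect_identical(s1, sample_background(mask, tw$presences, n = 100,
                                         seed = 5))
  expect_false(identical(s1, sample_background(mask, tw$presences, n = 100,
                                               seed = 6)))
  expect_error(sample_background(mask, tw$presences, n = 1e6), "shortfall")
})

test_that("depth stratification follows the largest-remainder quota", {
  set.seed(7)
  # presences 50/50 across two strata, 100 targets -> 50 + 50
  pres_d <- c(runif(40, 100, 240), runif(40, 260, 490))
  cand <- seq_len(2000)
  cand_d <- runif(2000, 100, 490)
  edges <- c(0, 250, 500)
  out <- depth_stratified_subsample(cand, cand_d, pres_d, edges, 100,
                                    seed = 1)
  expect_length(out, 100)
  expect_equal(as.vector(table(cut(cand_d[match(out, cand)], edges))),
               c(50, 50))

  # 70/20/10 proportions at n = 10000 -> 7000/2000/1000
  pres_d2 <- c(runif(70, 0, 240), runif(20, 260, 490), runif(10, 510, 740))
  cand_d2 <- runif(30000, 0, 750)
  out2 <- depth_stratified_subsample(seq_len(30000), cand_d2, pres_d2,
                                     c(0, 250, 500, 750), 10000, seed = 2)
  expect_equal(as.vector(table(cut(cand_d2[out2], c(0, 250, 500, 750)))),
               c(7000, 2000, 1000))

  # single stratum: plain subsample of the requested size
  out3 <- depth_stratified_subsample(cand, cand_d, pres_d, c(-Inf, Inf),
                                     500, seed = 3)
  expect_length(out3, 500)

  # empty stratum with positive target errors and names the stratum
  expect_error(
    depth_stratified_subsample(cand, runif(2000, 0, 240), pres_d2,
                               c(0, 250, 500, 750), 100),
    "insufficient background candidates")
})

test_that("full pseudo-absence chain matches the presence depth histogram", {
  bgd <- fx_background_default()
  depths <- bgd$present$layers$depth$values
  pa <- bgd$pa
  expect_length(pa, 10000)
  expect_length(intersect(pa, bgd$presences$cells), 0)

  qd <- quantile(depths[bgd$presences$cells], c(0.10, 0.90))
  edges <- c(-Inf, seq(floor(qd[1] / 250) * 250,
                       ceiling(qd[2] / 250) * 250, by = 250), Inf)
  p_prop <- table(cut(depths[bgd$presences$cells], edges)) /
    bgd$presences$n_cells
  a_prop <- table(cut(depths[pa], edges)) / length(pa)
  l1 <- sum(abs(as.vector(p_prop) - as.vector(a_prop)))
  expect_lte(l1, length(p_prop) / length(pa))
})

test_that("training assembly extracts covariates and drops missing rows", {
  fxw <- fx_world_small()
  st <- fxw$present
  occ <- simulate_occurrences(st, fx_niche(), 100, seed = 14)
  pres <- rasterize_presences(occ, fxw$grid)
  pa <- generate_pseudo_absences(pres, st, n_target = 1000,
                                 strata_edges = c(-Inf, Inf), seed = 14)
  tab <- assemble_training(pres, pa, st)
  expect_equal(nrow(tab), 1100)
  expect_setequal(unique(tab$label), c(0L, 1L))
  # extraction spot-check by direct indexing
  i <- 37
  expect_equal(tab$temp[i], st$layers$temp$values[tab$cell_id[i]])

  # a missing covariate on one background cell drops exactly that row
  st2 <- st
  st2$layers$temp$values[pa[1]] <- NA
  expect_message(tab2 <- assemble_training(pres, pa, st2), "dropped 1 row")
  expect_equal(nrow(tab2), 1099)

  expect_error(assemble_training(pres, c(pres$cells[1], pa), st), "overlap")
})
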