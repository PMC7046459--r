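make_plaque_map <- function(centers, r, nx, px = 1) {
  lab <- matrix(0L, nx, nx)
  xs <- matrix(seq_len(nx), nx, nx); ys <- t(xs)
  for (i in seq_len(nrow(centers))) {
    d2 <- (xs - centers[i, 1])^2 + (ys - centers[i, 2])^2
    lab[d2 <= r^2] <- i
  }
  label_map(lab, px)
}

test_that("a single plaque's influence zone is the whole frame", {
  lm <- make_plaque_map(cbind(30, 30), 6, 64)
  part <- watershed_partition(lm)
  expect_true(all(part$zones$data == 1L))
  expect_equal(part$n_plaques, 1)
})

test_that("two equal disks split the frame along the perpendicular bisector", {
  lm <- make_plaque_map(rbind(c(20, 32), c(44, 32)), 5, 64)
  part <- watershed_partition(lm)
  xs <- matrix(seq_len(64), 64, 64); ys <- t(xs)
  d1 <- sqrt((xs - 20)^2 + (ys - 32)^2)
  d2 <- sqrt((xs - 44)^2 + (ys - 32)^2)
  off_tie <- abs(d1 - d2) > 1.5     # away from the bisector
  oracle <- ifelse(d1 < d2, 1L, 2L)
  expect_true(all(part$zones$data[off_tie] == oracle[off_tie]))
  expect_true(all(part$zones$data[lm$data == 1L] == 1L))
  expect_true(all(part$zones$data[lm$data == 2L] == 2L))
})

test_that("empty plaque maps yield empty partitions, rings and tables", {
  lm <- label_map(matrix(0L, 32, 32), 1)
  part <- watershed_partition(lm)
  expect_equal(part$n_plaques, 0)
  rings <- constrained_dilation(lm, part)
  expect_equal(max(rings$data), 0)
  tab <- plaque_associated_fraction(binary_mask(matrix(FALSE, 32, 32), 1),
                                    lm, rings, "ring")
  expect_equal(nrow(tab), 0)
})

test_that("an isolated plaque ring matches the unconstrained brute-force oracle", {
  lm <- make_plaque_map(cbind(50, 50), 8, 100)
  rings <- constrained_dilation(lm, radius_um = 17)
  ring_idx <- which(rings$data == 1L)
  plaque_idx <- which(lm$data == 1L)
  d <- bf_min_dist_um(ring_idx, plaque_idx, 100, 1)
  expect_true(all(d <= 17 + sqrt(2)))          # within radius (+1 px diagonal)
  # oracle: every non-plaque pixel within 17 um must be in the ring
  all_idx <- which(lm$data == 0L)
  d_all <- bf_min_dist_um(all_idx, plaque_idx, 100, 1)
  oracle_idx <- all_idx[d_all <= 17]
  expect_lt(abs(length(oracle_idx) - length(ring_idx)) /
            length(oracle_idx), 0.02)          # one-pixel boundary band
  expect_true(all(ring_idx %in% all_idx[d_all <= 17 + sqrt(2)]))
})

test_that("rings of close plaques stay disjoint and inside their zones", {
  lm <- make_plaque_map(rbind(c(26, 32), c(42, 32)), 3, 64)  # 16 um apart
  part <- watershed_partition(lm)
  rings <- constrained_dilation(lm, part, 17)
  r1 <- rings$data == 1L; r2 <- rings$data == 2L
  expect_equal(sum(r1 & r2), 0)
  expect_true(all(part$zones$data[r1] == 1L))
  expect_true(all(part$zones$data[r2] == 2L))
})

test_that("enlarging the dilation radius never shrinks a ring", {
  sc <- make_scene(scene_spec(n_plaques = 5, width_um = 180, height_um = 180,
                              seed = 21, channels = "X04"))
  seg <- segment_fluorescence(sc$channels$X04)
  part <- watershed_partition(seg$labels)
  sizes <- vapply(c(5, 10, 17, 25), function(r)
    sum(constrained_dilation(seg$labels, part, r)$data > 0L), numeric(1))
  expect_true(all(diff(sizes) >= 0))
})

test_that("ring and plaque territories conserve frame area over random scenes", {
  for (seed in 1:10) {
    sc <- make_scene(scene_spec(n_plaques = 4, width_um = 128,
                                height_um = 128, seed = seed,
                                channels = "X04"))
    seg <- segment_fluorescence(sc$channels$X04)
    if (nrow(seg$table) == 0) next
    part <- watershed_partition(seg$labels)
    rings <- constrained_dilation(seg$labels, part, 17)
    n_covered <- sum(seg$labels$data > 0L) + sum(rings$data > 0L)
    expect_lte(n_covered, length(rings$data))
    expect_equal(sum(seg$labels$data > 0L & rings$data > 0L), 0)
  }
})

test_that("plaque-associated fractions follow the two normalization rules", {
  nx <- 40
  plaques <- matrix(0L, nx, nx); plaques[11:20, 11:20] <- 1L  # 100 px
  ring <- matrix(0L, nx, nx)
  ring[6:25, 6:10] <- 1L; ring[6:25, 21:25] <- 1L             # 200 px
  ring[6:10, 11:20] <- 1L                                     # +50 -> 250 px
  pl <- label_map(plaques, 1); rg <- label_map(ring, 1)

  # signal identical to ring, ring-normalized -> 1
  tab <- plaque_associated_fraction(binary_mask(ring > 0L, 1), pl, rg, "ring")
  expect_equal(tab$fraction, 1)
  # empty signal -> 0
  tab0 <- plaque_associated_fraction(binary_mask(matrix(FALSE, nx, nx), 1),
                                     pl, rg, "ring")
  expect_equal(tab0$fraction, 0)
  # half the ring plus all of the plaque, plaque-normalized -> 2.5
  sig <- plaques > 0L
  sig[6:25, 6:10] <- TRUE; sig[6:15, 21:25] <- TRUE           # 150 ring px
  tab25 <- plaque_associated_fraction(binary_mask(sig, 1), pl, rg, "plaque")
  expect_equal(tab25$fraction, 2.5)
  expect_equal(attr(tab25, "section_fraction"), 2.5)
})

test_that("percent area normalizes signal to tissue and ignores outside signal", {
  tissue <- binary_mask(rbind(matrix(TRUE, 20, 40), matrix(FALSE, 20, 40)), 1)
  expect_equal(percent_area(tissue, tissue), 100)
  none <- binary_mask(matrix(FALSE, 40, 40), 1)
  expect_equal(percent_area(none, tissue), 0)
  half <- tissue$data; half[11:20, ] <- FALSE
  expect_equal(percent_area(binary_mask(half, 1), tissue), 50)
  outside <- half; outside[21:40, ] <- TRUE   # add signal outside tissue
  expect_equal(percent_area(binary_mask(outside, 1), tissue), 50)
  expect_error(percent_area(tissue, none), "empty")
})

test_that("section values aggregate to animals by unweighted means", {
  out <- aggregate_sections(c(1, 3, 10), c("a", "a", "b"))
  expect_equal(out$value, c(2, 10))
  expect_equal(out$n_sections, c(2L, 1L))
})
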