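test_that("identical slabs register with identity transform and high score", {
  slab <- blob_slab(random_centers(15, seed = 3), seed = 3)
  tf <- register_visits(slab, slab)
  expect_lt(abs(tf$theta_rad), 0.01)
  expect_lt(max(abs(c(tf$tx_um, tf$ty_um))), 6)
  expect_gt(tf$score, 0.95)
})

test_that("known inter-visit shifts are recovered to sub-pixel accuracy", {
  slab <- blob_slab(random_centers(15, seed = 3), seed = 3)
  sh <- c(3L, -2L)  # pixels: content of the follow-up is baseline shifted
  img2 <- matrix(0.3, 160, 160)
  img2[(1 + sh[1]):160, 1:(160 + sh[2])] <-
    slab$img[1:(160 - sh[1]), (1 - sh[2]):160]
  follow <- slab; follow$img <- img2; follow$visit <- "f"
  tf <- register_visits(slab, follow, rot_step_deg = 0)
  expect_lt(abs(tf$tx_um / 12 - sh[1]), 0.5)
  expect_lt(abs(tf$ty_um / 12 - sh[2]), 0.5)
  # the transform maps baseline coordinates onto the shifted content
  p <- apply_visit_transform(tf, 600, 600)
  expect_equal(as.numeric(p), c(600 + sh[1] * 12, 600 + sh[2] * 12),
               tolerance = 0.5)
  back <- apply_visit_transform(tf, p[1], p[2], inverse = TRUE)
  expect_equal(as.numeric(back), c(600, 600), tolerance = 1e-6)
})

test_that("structureless image pairs are reported unregistrable", {
  set.seed(7)
  n1 <- blob_slab(data.frame(x_um = numeric(), y_um = numeric()), texture = 0)
  n2 <- n1
  n1$img <- matrix(runif(160 * 160), 160, 160)
  n2$img <- matrix(runif(160 * 160), 160, 160)
  expect_error(register_visits(n1, n2), "unregistrable")
})

test_that("blob detection finds seeded dots and nothing on uniform slabs", {
  cents <- random_centers(20, seed = 5)
  slab <- blob_slab(cents, seed = 5)
  det <- detect_sdd(slab)
  expect_equal(nrow(det), 20L)
  dmin <- vapply(seq_len(nrow(det)), function(i)
    min(sqrt((cents$x_um - det$x_um[i])^2 + (cents$y_um - det$y_um[i])^2)),
    numeric(1))
  expect_lt(max(dmin), 12)  # within one pixel of a true centre
  uniform <- blob_slab(cents[0, ], texture = 0)
  expect_equal(nrow(detect_sdd(uniform)), 0L)
})

test_that("detections on a 180-degree rotated slab correspond under rotation", {
  cents <- random_centers(12, seed = 11)
  slab <- blob_slab(cents, seed = 11)
  rot <- slab
  rot$img <- slab$img[160:1, 160:1]
  d1 <- detect_sdd(slab)
  d2 <- detect_sdd(rot)
  expect_equal(nrow(d1), nrow(d2))
  span <- 159 * 12
  for (i in seq_len(nrow(d1))) {
    dd <- sqrt((span - d2$x_um - d1$x_um[i])^2 +
               (span - d2$y_um - d1$y_um[i])^2)
    expect_lt(min(dd), 12)
  }
})

test_that("simple change configurations classify as published", {
  empty <- tibble::tibble(id = integer(), x_um = numeric(), y_um = numeric())
  expect_equal(nrow(classify_changes(empty, empty, NULL, 60)), 0L)
  b3 <- tibble::tibble(id = 1:3, x_um = c(100, 500, 900),
                       y_um = c(100, 500, 900))
  expect_true(all(classify_changes(b3, b3, NULL, 60)$category == "stable"))
  # unmatched baseline regresses; unmatched follow-up is new
  f1 <- b3[1, ]
  rec <- classify_changes(b3, f1, NULL, 60)
  expect_equal(sort(rec$category), c("regressed", "regressed", "stable"))
  rec2 <- classify_changes(f1, b3, NULL, 60)
  expect_equal(sort(rec2$category), c("new", "new", "stable"))
  # two baselines sharing one follow-up fuse
  b2 <- tibble::tibble(id = 1:2, x_um = c(100, 160), y_um = c(100, 100))
  fm <- tibble::tibble(id = 1L, x_um = 130, y_um = 100)
  expect_true(all(classify_changes(b2, fm, NULL, 60)$category == "fused"))
  expect_error(classify_changes(b3, b3, NULL, 0), "radius")
})

test_that("classification agrees with the brute-force oracle on random
           configurations", {
  set.seed(123)
  for (rep in seq_len(1000)) {
    nb <- sample(0:6, 1); nf <- sample(0:6, 1)
    base <- tibble::tibble(id = seq_len(nb),
                           x_um = runif(nb, 0, 500),
                           y_um = runif(nb, 0, 500))
    follow <- tibble::tibble(id = seq_len(nf),
                             x_um = runif(nf, 0, 500),
                             y_um = runif(nf, 0, 500))
    rec <- classify_changes(base, follow, NULL, 60)
    orc <- oracle_classify(base, follow, 60)
    got_base <- rec$category[match(seq_len(nb), rec$base_id)]
    expect_identical(unname(got_base), orc$base_categories)
    expect_identical(sum(rec$category == "new"), as.integer(orc$n_new))
  }
})

test_that("classification is invariant under relabelling of detection ids", {
  set.seed(9)
  base <- tibble::tibble(id = 1:5, x_um = runif(5, 0, 400),
                         y_um = runif(5, 0, 400))
  follow <- tibble::tibble(id = 1:4, x_um = runif(4, 0, 400),
                           y_um = runif(4, 0, 400))
  rec <- classify_changes(base, follow, NULL, 80)
  perm <- sample(5); permf <- sample(4)
  base2 <- base[perm, ]; base2$id <- seq_len(5)
  follow2 <- follow[permf, ]; follow2$id <- seq_len(4)
  rec2 <- classify_changes(base2, follow2, NULL, 80)
  # same multiset of categories regardless of input ordering/ids
  expect_identical(sort(rec$category), sort(rec2$category))
})

test_that("quadrants follow the fundus convention with tie-breaks", {
  # OD: nasal is toward smaller x; superior is smaller y
  expect_equal(assign_quadrant(100, 100, c(500, 500), "OD"), "superonasal")
  expect_equal(assign_quadrant(900, 900, c(500, 500), "OD"),
               "inferotemporal")
  expect_equal(assign_quadrant(100, 100, c(500, 500), "OS"),
               "superotemporal")
  # ties break toward superior and nasal
  expect_equal(assign_quadrant(500, 500, c(500, 500), "OD"), "superonasal")
  # mirroring x about the fovea swaps nasal/temporal, keeps superior
  set.seed(4)
  x <- runif(50, 0, 1000); y <- runif(50, 0, 1000)
  q <- assign_quadrant(x, y, c(500, 500), "OD")
  qm <- assign_quadrant(1000 - x, y, c(500, 500), "OD")
  swap <- function(z) ifelse(grepl("nasal", z),
                             sub("nasal", "temporal", z),
                             sub("temporal", "nasal", z))
  ties <- x == 500
  expect_identical(qm[!ties], swap(q)[!ties])
})

test_that("quadrant counts match an independent sign-based reimplementation", {
  set.seed(14)
  x <- runif(200, 0, 2000); y <- runif(200, 0, 2000)
  fovea <- c(950, 1030)
  for (lat in c("OD", "OS")) {
    q <- assign_quadrant(x, y, fovea, lat)
    sup <- y <= fovea[2]
    nas <- if (lat == "OD") x <= fovea[1] else x >= fovea[1]
    ref <- paste0(ifelse(sup, "supero", "infero"),
                  ifelse(nas, "nasal", "temporal"))
    expect_identical(as.character(table(q)[sort(unique(ref))]),
                     as.character(table(ref)[sort(unique(ref))]))
  }
})

test_that("summaries reproduce printed percentages and stay consistent", {
  rec <- tibble::tibble(
    category = rep(c("stable", "regressed", "fused", "new"),
                   c(278, 32, 11, 5)),
    quadrant = rep(c("superonasal", "superotemporal", "inferonasal",
                     "inferotemporal"), c(86, 83, 79, 78)))
  s <- summarize_changes(rec)
  expect_equal(s$total, 326L)
  expect_equal(s$categories$pct, c(85.3, 9.8, 3.4, 1.5))
  expect_equal(s$quadrants$pct, c(26.4, 25.5, 24.2, 23.9))
  expect_equal(sum(s$categories$n), s$total)
  expect_lt(abs(sum(s$categories$pct) - 100), 0.2)
  expect_lt(abs(sum(s$quadrants$pct) - 100), 0.2)
  # single stable record
  one <- summarize_changes(tibble::tibble(category = "stable",
                                          quadrant = NA_character_))
  expect_equal(one$categories$pct[1], 100.0)
  # empty input: zero counts, masked percentages
  zero <- summarize_changes(tibble::tibble(category = character(),
                                           quadrant = character()))
  expect_equal(zero$total, 0L)
  expect_true(all(is.na(zero$categories$pct)))
  # tidiers
  td <- tidy(s)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 8L)
  gl <- glance(s)
  expect_equal(gl$pct_stable, 85.3)
})

test_that("percentage rounding is half-up at one decimal", {
  expect_equal(round_half_up(0.05, 1), 0.1)
  expect_equal(round_half_up(85.25, 1), 85.3)
  expect_equal(round_half_up(c(9.8159, 3.3742, 1.5337) * 1, 1),
               c(9.8, 3.4, 1.5))
})
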