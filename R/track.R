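#' Register en face slabs across visits
#'
#' Rigid 2D registration: phase-correlation initialization of the
#' translation, followed by a small-angle rotation refinement maximizing
#' normalized cross-correlation, with parabolic sub-pixel/sub-degree
#' interpolation. The transform maps baseline coordinates into the
#' follow-up frame: `p' = R(theta) (p - c) + c + t` about the image centre
#' `c`.
#'
#' @param baseline,followup `enface_slab`s with the same pixel pitch.
#' @param max_rot_deg rotation search bound (degrees).
#' @param rot_step_deg rotation search step (degrees); 0 disables rotation.
#' @param score_floor minimum acceptable normalized cross-correlation.
#' @return a `visit_transform` with `theta_rad`, `tx_um`, `ty_um`,
#'   `center_um` and the registration `score`.
#' @export
register_visits <- function(baseline, followup, max_rot_deg = 5,
                            rot_step_deg = 1, score_floor = 0.2) {
  stopifnot(inherits(baseline, "enface_slab"), inherits(followup, "enface_slab"))
  if (abs(baseline$pitch_um - followup$pitch_um) > 1e-9)
    stopf("slabs have different pixel pitch")
  a <- norm_img(baseline$img); b <- norm_img(followup$img)
  angles <- if (rot_step_deg > 0) seq(-max_rot_deg, max_rot_deg, by = rot_step_deg) else 0
  cx <- (nrow(a) - 1) / 2; cy <- (ncol(a) - 1) / 2
  best <- list(score = -Inf)
  scores <- numeric(length(angles))
  for (k in seq_along(angles)) {
    th <- angles[k] * pi / 180
    ar <- if (th != 0) rotate2d_cpp(a, th, cx, cy, 0) else a
    pc <- phase_corr(ar, b)
    scores[k] <- pc$score
    if (pc$score > best$score)
      best <- list(score = pc$score, shift = pc$shift, theta = th, k = k)
  }
  # parabolic refinement of the rotation on the NCC samples
  th <- best$theta
  if (length(angles) > 2 && best$k > 1 && best$k < length(angles)) {
    off <- parabolic_offset(-scores[best$k - 1], -scores[best$k],
                            -scores[best$k + 1])
    th <- (angles[best$k] + off * rot_step_deg) * pi / 180
  }
  if (!is.finite(best$score) || best$score < score_floor)
    stopf("visits unregistrable (score %.3f below floor %.3f)",
          max(best$score, -1), score_floor)
  pitch <- baseline$pitch_um
  structure(list(theta_rad = th, tx_um = best$shift[1] * pitch,
                 ty_um = best$shift[2] * pitch,
                 center_um = c(cx, cy) * pitch, score = best$score),
            class = "visit_transform")
}

norm_img <- function(m) {
  m[!is.finite(m)] <- median(m, na.rm = TRUE)
  m <- m - mean(m)
  s <- sd(m)
  if (s > 0) m / s else m
}

# translation estimate by phase correlation with parabolic sub-pixel peak;
# score is the normalized cross-correlation at the estimated shift
phase_corr <- function(a, b) {
  d <- dim(a)
  fa <- fft(a); fb <- fft(b)
  cross <- fb * Conj(fa)
  r <- Re(fft(cross / pmax(Mod(cross), 1e-12), inverse = TRUE))
  pk <- arrayInd(which.max(r), d)
  wrap <- function(i, n) ifelse(i - 1 > n / 2, i - 1 - n, i - 1)
  sx <- wrap(pk[1], d[1]); sy <- wrap(pk[2], d[2])
  sub <- c(0, 0)
  gx <- function(i, j) r[(i - 1) %% d[1] + 1, (j - 1) %% d[2] + 1]
  sub[1] <- parabolic_offset(-gx(pk[1] - 1, pk[2]), -gx(pk[1], pk[2]),
                             -gx(pk[1] + 1, pk[2]))
  sub[2] <- parabolic_offset(-gx(pk[1], pk[2] - 1), -gx(pk[1], pk[2]),
                             -gx(pk[1], pk[2] + 1))
  shift <- c(sx + sub[1], sy + sub[2])
  score <- ncc_at_shift(a, b, round(shift))
  list(shift = shift, score = score)
}

ncc_at_shift <- function(a, b, s) {
  d <- dim(a)
  x0 <- max(1, 1 + s[1]); x1 <- min(d[1], d[1] + s[1])
  y0 <- max(1, 1 + s[2]); y1 <- min(d[2], d[2] + s[2])
  if (x1 - x0 < 8 || y1 - y0 < 8) return(-1)
  bb <- b[x0:x1, y0:y1]
  aa <- a[(x0:x1) - s[1], (y0:y1) - s[2]]
  va <- sd(aa); vb <- sd(bb)
  if (va == 0 || vb == 0) return(0)
  mean((aa - mean(aa)) * (bb - mean(bb))) / (va * vb)
}

#' Map baseline coordinates through a visit transform
#' @param tf a `visit_transform`.
#' @param x_um,y_um baseline-frame coordinates (um).
#' @param inverse map follow-up coordinates back to the baseline frame.
#' @return a two-column matrix of transformed coordinates (um).
#' @export
apply_visit_transform <- function(tf, x_um, y_um, inverse = FALSE) {
  th <- tf$theta_rad
  c1 <- tf$center_um[1]; c2 <- tf$center_um[2]
  if (!inverse) {
    dx <- x_um - c1; dy <- y_um - c2
    cbind(x_um = cos(th) * dx - sin(th) * dy + c1 + tf$tx_um,
          y_um = sin(th) * dx + cos(th) * dy + c2 + tf$ty_um)
  } else {
    dx <- x_um - tf$tx_um - c1; dy <- y_um - tf$ty_um - c2
    cbind(x_um = cos(th) * dx + sin(th) * dy + c1,
          y_um = -sin(th) * dx + cos(th) * dy + c2)
  }
}

#' @export
print.visit_transform <- function(x, ...) {
  cat(sprintf("<visit_transform> rot %.2f deg, shift (%.1f, %.1f) um, score %.3f\n",
              x$theta_rad * 180 / pi, x$tx_um, x$ty_um, x$score))
  invisible(x)
}

#' Detect dot SDDs on an en face slab
#'
#' Scale-space blob detection: the background-subtracted slab is filtered
#' with a difference-of-Gaussians approximation of the scale-normalized
#' Laplacian over blob radii 25-125 um; local maxima above the contrast
#' threshold are kept after non-maximum suppression by centre distance.
#'
#' @param slab an `enface_slab`.
#' @param r_min_um,r_max_um blob radius range (um).
#' @param n_scales number of scales (geometric progression).
#' @param contrast_min peak response threshold, relative to the slab's
#'   robust brightness.
#' @param overlap suppression radius as a fraction of the blob radius sum.
#' @param margin_um detections closer than this to the image border or to
#'   masked (uncovered) pixels are discarded.
#' @return a tibble of detections: `id`, `x_um`, `y_um`, `diameter_um`,
#'   `contrast`, `visit`.
#' @export
detect_sdd <- function(slab, r_min_um = 25, r_max_um = 125, n_scales = 6L,
                       contrast_min = 0.15, overlap = 0.5, margin_um = 36) {
  stopifnot(inherits(slab, "enface_slab"))
  pitch <- slab$pitch_um
  img <- slab$img
  masked <- !is.finite(img)
  level <- median(img, na.rm = TRUE)
  img[masked] <- level
  sig_cap <- (min(dim(img)) - 1) / 8  # EBImage brush must fit the image
  bg_sigma <- min(2 * r_max_um / pitch, sig_cap)
  bg <- EBImage::imageData(EBImage::gblur(img, sigma = bg_sigma))
  im <- img - bg
  sigmas <- exp(seq(log(r_min_um), log(r_max_um), length.out = n_scales)) /
    (sqrt(2) * pitch)
  sigmas <- sigmas[sigmas * 1.6 <= sig_cap]
  if (!length(sigmas)) sigmas <- sig_cap / 1.6
  k <- 1.6
  peaks <- list()
  for (s in sigmas) {
    g1 <- EBImage::imageData(EBImage::gblur(im, sigma = s))
    g2 <- EBImage::imageData(EBImage::gblur(im, sigma = s * k))
    resp <- (g1 - g2)
    mx <- local_maxima(resp)
    thr <- contrast_min * max(level, 1e-12)
    sel <- which(mx & resp > thr, arr.ind = TRUE)
    if (nrow(sel)) {
      peaks[[length(peaks) + 1]] <- tibble(
        xi = sel[, 1], yi = sel[, 2],
        resp = resp[sel], sigma_px = s)
    }
  }
  if (!length(peaks)) {
    return(tibble(id = integer(), x_um = numeric(), y_um = numeric(),
                  diameter_um = numeric(), contrast = numeric(),
                  visit = character()))
  }
  det <- dplyr::arrange(dplyr::bind_rows(peaks), dplyr::desc(.data$resp))
  # sub-pixel centroid on the response in a 3x3 neighbourhood
  cx <- numeric(nrow(det)); cy <- numeric(nrow(det))
  for (i in seq_len(nrow(det))) {
    xi <- det$xi[i]; yi <- det$yi[i]
    cx[i] <- xi - 1 + centroid_offset(im, xi, yi, 1)
    cy[i] <- yi - 1 + centroid_offset(t(im), yi, xi, 1)
  }
  det$x_um <- cx * pitch; det$y_um <- cy * pitch
  det$r_um <- det$sigma_px * sqrt(2) * pitch
  # discard peaks hugging the border or masked regions (edge artifacts)
  mpx <- ceiling(margin_um / pitch)
  ok <- det$xi > mpx & det$xi <= nrow(img) - mpx &
    det$yi > mpx & det$yi <= ncol(img) - mpx
  if (any(masked)) {
    for (i in which(ok)) {
      xr <- max(1, det$xi[i] - mpx):min(nrow(img), det$xi[i] + mpx)
      yr <- max(1, det$yi[i] - mpx):min(ncol(img), det$yi[i] + mpx)
      if (any(masked[xr, yr])) ok[i] <- FALSE
    }
  }
  det <- det[ok, ]
  if (!nrow(det)) {
    return(tibble(id = integer(), x_um = numeric(), y_um = numeric(),
                  diameter_um = numeric(), contrast = numeric(),
                  visit = character()))
  }
  keep <- rep(TRUE, nrow(det))
  for (i in seq_len(nrow(det))) {
    if (!keep[i]) next
    if (i < nrow(det)) {
      jj <- (i + 1):nrow(det)
      dd <- sqrt((det$x_um[jj] - det$x_um[i])^2 + (det$y_um[jj] - det$y_um[i])^2)
      keep[jj][dd < overlap * (det$r_um[jj] + det$r_um[i])] <- FALSE
    }
  }
  det <- det[keep, ]
  tibble(id = seq_len(nrow(det)), x_um = det$x_um, y_um = det$y_um,
         diameter_um = 2 * det$r_um, contrast = det$resp,
         visit = rep(slab$visit %||% NA_character_, nrow(det)))
}

local_maxima <- function(m) {
  d <- dim(m)
  pad <- matrix(-Inf, d[1] + 2, d[2] + 2)
  pad[2:(d[1] + 1), 2:(d[2] + 1)] <- m
  out <- matrix(TRUE, d[1], d[2])
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    out <- out & (m >= pad[2:(d[1] + 1) + di, 2:(d[2] + 1) + dj])
  }
  out & is.finite(m)
}

centroid_offset <- function(im, xi, yi, h) {
  if (xi <= h || xi > nrow(im) - h) return(0)
  v <- im[(xi - h):(xi + h), yi]
  v <- v - min(v)
  if (sum(v) <= 0) return(0)
  sum((-h:h) * v) / sum(v)
}

#' Classify longitudinal SDD changes between two visits
#'
#' Baseline detections are mapped through the visit transform; each is
#' assigned its nearest follow-up detection within the match radius.
#' Baselines sharing one nearest follow-up are labelled `fused`; a
#' baseline whose nearest follow-up reciprocates (mutual nearest
#' neighbour) is `stable`; a baseline with no follow-up within the radius
#' -- or whose candidate prefers another baseline -- is `regressed`;
#' follow-up detections claimed by no baseline are `new`. Distance ties
#' are broken toward the lower detection id.
#'
#' @param base,follow detection tibbles from [detect_sdd()] (deduplicated
#'   per visit).
#' @param tf a `visit_transform` mapping baseline to follow-up frame, or
#'   `NULL` for identity.
#' @param radius_um match radius (um).
#' @return a tibble of change records: `category`
#'   (stable/regressed/fused/new), `base_id`, `follow_id`, baseline-frame
#'   `x_um`, `y_um` (inverse-mapped for new SDDs), and `quadrant` (NA
#'   until [add_quadrants()]).
#' @export
classify_changes <- function(base, follow, tf = NULL, radius_um = 60) {
  if (radius_um <= 0) stopf("match radius must be positive")
  nb <- nrow(base); nf <- nrow(follow)
  if (nb == 0 && nf == 0) {
    return(tibble(category = character(), base_id = integer(),
                  follow_id = integer(), x_um = numeric(), y_um = numeric(),
                  quadrant = character()))
  }
  bm <- if (nb > 0 && !is.null(tf)) {
    apply_visit_transform(tf, base$x_um, base$y_um)
  } else if (nb > 0) cbind(base$x_um, base$y_um) else matrix(0, 0, 2)
  nearest <- rep(NA_integer_, nb)
  if (nb > 0 && nf > 0) {
    for (i in seq_len(nb)) {
      dd <- sqrt((follow$x_um - bm[i, 1])^2 + (follow$y_um - bm[i, 2])^2)
      j <- which.min(dd)  # lowest index on ties
      if (dd[j] <= radius_um) nearest[i] <- j
    }
  }
  cat_b <- rep("regressed", nb)
  share <- table(nearest[!is.na(nearest)])
  for (i in seq_len(nb)) {
    j <- nearest[i]
    if (is.na(j)) next
    if (share[as.character(j)] >= 2) {
      cat_b[i] <- "fused"
    } else {
      # mutual nearest neighbour check for a 1:1 match
      db <- sqrt((bm[, 1] - follow$x_um[j])^2 + (bm[, 2] - follow$y_um[j])^2)
      if (which.min(db) == i && db[i] <= radius_um) cat_b[i] <- "stable"
    }
  }
  matched_f <- unique(nearest[!is.na(nearest)])
  new_f <- setdiff(seq_len(nf), matched_f)
  rec_b <- if (nb > 0) {
    tibble(category = cat_b, base_id = base$id,
           follow_id = ifelse(is.na(nearest), NA_integer_,
                              follow$id[nearest]),
           x_um = base$x_um, y_um = base$y_um)
  } else NULL
  rec_n <- if (length(new_f)) {
    pos <- if (!is.null(tf)) {
      apply_visit_transform(tf, follow$x_um[new_f], follow$y_um[new_f],
                            inverse = TRUE)
    } else cbind(follow$x_um[new_f], follow$y_um[new_f])
    tibble(category = "new", base_id = NA_integer_,
           follow_id = follow$id[new_f], x_um = pos[, 1], y_um = pos[, 2])
  } else NULL
  out <- dplyr::bind_rows(rec_b, rec_n)
  out$quadrant <- NA_character_
  out
}

#' Assign macular quadrants relative to the fovea
#'
#' Fundus-view convention: smaller y (row) is superior; for a right eye
#' (OD) nasal is toward smaller x, for a left eye (OS) toward larger x.
#' Ties (a detection exactly on an axis) are broken toward superior and
#' nasal.
#'
#' @param x_um,y_um detection coordinates (um, slab frame).
#' @param fovea length-2 fovea position (um).
#' @param laterality `"OD"` or `"OS"`.
#' @return character vector of quadrants (`superonasal`, `superotemporal`,
#'   `inferonasal`, `inferotemporal`).
#' @export
assign_quadrant <- function(x_um, y_um, fovea, laterality = c("OD", "OS")) {
  laterality <- match.arg(laterality)
  dy <- y_um - fovea[2]
  dx <- x_um - fovea[1]
  sup <- dy <= 0
  nasal <- if (laterality == "OS") dx >= 0 else dx <= 0
  paste0(ifelse(sup, "supero", "infero"), ifelse(nasal, "nasal", "temporal"))
}

#' Add quadrant labels to change records
#' @param records tibble from [classify_changes()].
#' @param fovea length-2 fovea position (um, baseline frame).
#' @param laterality `"OD"` or `"OS"`.
#' @return the records with the `quadrant` column filled.
#' @export
add_quadrants <- function(records, fovea, laterality = c("OD", "OS")) {
  laterality <- match.arg(laterality)
  records$quadrant <- assign_quadrant(records$x_um, records$y_um, fovea,
                                      laterality)
  records
}

QUADRANTS <- c("superonasal", "superotemporal", "inferonasal", "inferotemporal")
CATEGORIES <- c("stable", "regressed", "fused", "new")

#' Summarize tracked SDD changes
#'
#' Per-category counts and percentages (round-half-up to one decimal) over
#' the total tracked SDDs, plus the quadrant distribution of the records.
#'
#' @param records tibble of change records (one row per tracked SDD).
#' @return an `sdd_summary`: `categories` and `quadrants` tibbles and the
#'   `total`.
#' @export
summarize_changes <- function(records) {
  total <- nrow(records)
  cats <- tibble(category = CATEGORIES,
                 n = vapply(CATEGORIES, function(cc)
                   sum(records$category == cc), integer(1),
                   USE.NAMES = FALSE))
  cats$pct <- if (total > 0) round_half_up(100 * cats$n / total, 1) else NA_real_
  qr <- records$quadrant[!is.na(records$quadrant)]
  qtot <- length(qr)
  quads <- tibble(quadrant = QUADRANTS,
                  n = vapply(QUADRANTS, function(qq) sum(qr == qq),
                    integer(1), USE.NAMES = FALSE))
  quads$pct <- if (qtot > 0) round_half_up(100 * quads$n / qtot, 1) else NA_real_
  structure(list(categories = cats, quadrants = quads, total = total,
                 quadrant_total = qtot),
            class = "sdd_summary")
}

#' @export
print.sdd_summary <- function(x, ...) {
  cat(sprintf("<sdd_summary> %d tracked SDDs\n", x$total))
  for (i in seq_len(nrow(x$categories)))
    cat(sprintf("  %-10s %4d  %5.1f%%\n", x$categories$category[i],
                x$categories$n[i], x$categories$pct[i]))
  if (x$quadrant_total > 0) {
    cat(sprintf("  quadrants (n = %d):\n", x$quadrant_total))
    for (i in seq_len(nrow(x$quadrants)))
      cat(sprintf("  %-15s %4d  %5.1f%%\n", x$quadrants$quadrant[i],
                  x$quadrants$n[i], x$quadrants$pct[i]))
  }
  invisible(x)
}

#' Broom-style tidiers
#'
#' `tidy()` returns the long per-level table of an object; `glance()` a
#' one-row overview.
#'
#' @param x the object.
#' @param ... unused.
#' @return a tibble.
#' @name tidy_methods
NULL

#' @rdname tidy_methods
#' @export
tidy.sdd_summary <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(dplyr::rename(x$categories, level = "category"),
                  table = "category", .before = 1),
    dplyr::mutate(dplyr::rename(x$quadrants, level = "quadrant"),
                  table = "quadrant", .before = 1))
}

#' @rdname tidy_methods
#' @export
glance.sdd_summary <- function(x, ...) {
  v <- setNames(as.list(x$categories$pct),
                paste0("pct_", x$categories$category))
  dplyr::bind_cols(tibble(total = x$total), tibble::as_tibble(v))
}

#' @rdname autoplot_methods
#' @export
autoplot.sdd_summary <- function(object, ...) {
  df <- object$categories
  df$category <- factor(df$category, levels = CATEGORIES)
  ggplot2::ggplot(df, ggplot2::aes(.data$category, .data$pct)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "% of tracked SDDs")
}
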