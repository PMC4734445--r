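#' Schematic lateral skull configuration
#'
#' Deterministic 2D landmark roster emulating a saurischian skull in
#' lateral view: 20 fixed landmarks at sutural contacts and extremities
#' (snout tip, alveolar margin, jaw joint, quadrate, skull-roof contacts,
#' opening corners) and 51 semilandmarks placed equidistantly along the
#' skull outline and the margins of the external naris, antorbital
#' fenestra, orbit and infratemporal fenestra. For `k_landmarks != 71` the
#' per-region counts are rescaled proportionally (at least 4 fixed
#' landmarks). The x axis is anteroposterior (snout at x = 0), y is up,
#' units are arbitrary.
#'
#' @param k_landmarks total number of points (>= 10; default 71).
#' @return a `landmark_config` (stage `"adult"`) with attribute `regions`,
#'   a character vector partitioning the landmarks into `fixed`,
#'   `outline`, `naris`, `antorbital`, `orbit`, `infratemporal`.
#' @export
make_base_skull <- function(k_landmarks = 71L) {
  k_landmarks <- as.integer(k_landmarks)
  if (k_landmarks < 10L) stop("need at least 10 landmarks")
  fixed <- matrix(c(
    0.0, 0.5,   # premaxilla tip
    0.3, 0.0,   # premaxilla alveolar margin
    4.5, 0.0,   # maxilla-jugal contact, ventral margin
    6.5, 0.2,   # jugal-quadratojugal contact
    7.8, 0.1,   # jaw joint (ventral quadrate)
    8.2, 1.2,   # quadrate head
    8.0, 2.2,   # squamosal
    6.8, 2.8,   # postorbital, dorsal
    5.2, 3.0,   # frontal above orbit
    3.8, 2.9,   # prefrontal/lacrimal, dorsal
    2.2, 2.2,   # nasal, mid-dorsal
    0.8, 1.3,   # ascending process of premaxilla
    1.0, 0.8,   # naris, anterior corner
    1.8, 1.1,   # naris, posterior corner
    2.6, 0.6,   # antorbital fossa, anterior margin
    3.6, 1.4,   # antorbital fenestra, anterodorsal corner
    4.4, 1.5,   # descending process of lacrimal
    5.0, 1.2,   # ascending process of jugal, orbital margin
    6.0, 1.0,   # postorbital bar, ventral
    7.0, 0.6),  # infratemporal fenestra, ventral margin
    ncol = 2L, byrow = TRUE)
  outline_waypoints <- matrix(c(
    0.0, 0.5,  0.8, 1.3,  2.2, 2.2,  3.8, 2.9,  5.2, 3.0,  6.8, 2.8,
    8.0, 2.2,  8.2, 1.2,  7.8, 0.1,  6.5, 0.2,  4.5, 0.0,  0.3, 0.0,
    0.0, 0.5), ncol = 2L, byrow = TRUE)
  base_counts <- c(fixed = 20L, outline = 21L, naris = 6L,
                   antorbital = 8L, orbit = 8L, infratemporal = 8L)
  counts <- if (k_landmarks == 71L) base_counts else
    rescale_counts(base_counts, k_landmarks)
  pts <- list(fixed = fixed[seq_len(counts["fixed"]), , drop = FALSE])
  if (counts["outline"] > 0L)
    pts$outline <- polyline_points(outline_waypoints, counts["outline"])
  ellipses <- list(naris = c(1.4, 0.95, 0.45, 0.28),
                   antorbital = c(3.5, 0.9, 0.8, 0.5),
                   orbit = c(5.6, 1.8, 0.65, 0.8),
                   infratemporal = c(7.0, 1.2, 0.55, 0.75))
  for (nm in names(ellipses)) {
    if (counts[nm] > 0L) {
      e <- ellipses[[nm]]
      t <- 2 * pi * (seq_len(counts[nm]) - 1L) / counts[nm]
      pts[[nm]] <- cbind(e[1] + e[3] * cos(t), e[2] + e[4] * sin(t))
    }
  }
  coords <- do.call(rbind, pts)
  regions <- rep(names(pts), vapply(pts, nrow, integer(1)))
  cfg <- landmark_configuration(
    coords, specimen_id = "base_skull", taxon = "base", stage = "adult",
    is_semilandmark = regions != "fixed")
  attr(cfg, "regions") <- regions
  cfg
}

rescale_counts <- function(base, k) {
  n_fixed <- min(base[["fixed"]], max(4L, round(base[["fixed"]] * k / sum(base))))
  rest <- base[-1L]
  target <- k - n_fixed
  raw <- rest / sum(rest) * target
  cnt <- floor(raw)
  rem <- target - sum(cnt)
  if (rem > 0L) {
    ord <- order(raw - cnt, decreasing = TRUE)
    cnt[ord[seq_len(rem)]] <- cnt[ord[seq_len(rem)]] + 1L
  }
  cnt <- stats::setNames(as.integer(cnt), names(rest))
  c(fixed = as.integer(n_fixed), cnt)
}

# n points equally spaced by arc length along a polyline, offset half a
# step so they do not coincide with the fixed waypoints.
polyline_points <- function(wp, n) {
  seg <- sqrt(rowSums(diff(wp)^2))
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  s <- (seq_len(n) - 0.5) / n * total
  t(vapply(s, function(si) {
    i <- findInterval(si, cum, rightmost.closed = TRUE)
    f <- (si - cum[i]) / seg[i]
    wp[i, ] + f * (wp[i + 1L, ] - wp[i, ])
  }, numeric(2L)))
}

#' Ground truth for synthetic ontogenetic/phylogenetic data
#'
#' Bundles the parameters of the generative model: a base shape (centered,
#' unit centroid size), a unit allometric axis orthogonal to the
#' translation/rotation/scaling null directions at the base shape, the
#' allometric slope (Procrustes units of shape change per unit log
#' centroid size), a Brownian-motion rate for adult mean shapes (variance
#' per coordinate per Myr, projected off the nuisance directions), a
#' Brownian rate for log centroid size, per-branch heterochronic shifts
#' (signed Procrustes-unit magnitudes along the allometric axis, named by
#' the tip or internal-node label whose subtending branch carries the
#' shift), isotropic per-landmark digitization noise (in units of centroid
#' size, default 0.5%), and a seed.
#'
#' @param base a `landmark_config` (default [make_base_skull()]).
#' @param allometric_vector optional 2k unit vector; drawn reproducibly
#'   from `seed` when omitted.
#' @param allometric_slope shape change per unit log CS (default 0.05).
#' @param bm_rate shape Brownian variance per coordinate per Myr
#'   (default 1e-8; baseline drift is kept below the digitization-noise
#'   floor so that injected heterochronic shifts are the identifiable
#'   source of divergence along the allometric axis).
#' @param bm_rate_logcs Brownian variance of log CS per Myr (default 2e-3).
#' @param heterochrony_shifts named numeric vector (default none).
#' @param noise_sd per-landmark digitization displacement sd, as a
#'   fraction of centroid size (default 0.005, i.e. 0.5%; the order of
#'   magnitude of careful manual digitization error).
#' @param log_cs_ref log CS at which a stage's shape equals the lineage
#'   mean shape (default 2, i.e. an adult-sized reference).
#' @param seed integer seed (default 1).
#' @return object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(base = make_base_skull(),
                            allometric_vector = NULL,
                            allometric_slope = 0.05,
                            bm_rate = 1e-8,
                            bm_rate_logcs = 2e-3,
                            heterochrony_shifts = numeric(0),
                            noise_sd = 0.005,
                            log_cs_ref = 2,
                            seed = 1L) {
  base_unit <- unit_shape(base$coords)
  Q <- nuisance_basis(base_unit)
  if (is.null(allometric_vector)) {
    old <- local_seed(seed); on.exit(restore_seed(old))
    v <- stats::rnorm(length(base_unit))
  } else v <- as.numeric(allometric_vector)
  v <- v - Q %*% crossprod(Q, v)
  nv <- sqrt(sum(v^2))
  if (nv <= 1e-12)
    stop("allometric vector lies in the translation/rotation/scale null space")
  structure(list(base = base,
                 base_shape = base_unit,
                 allometric_vector = as.vector(v / nv),
                 allometric_slope = allometric_slope,
                 bm_rate = bm_rate,
                 bm_rate_logcs = bm_rate_logcs,
                 heterochrony_shifts = heterochrony_shifts,
                 noise_sd = noise_sd,
                 log_cs_ref = log_cs_ref,
                 nuisance_basis = Q,
                 seed = as.integer(seed)),
            class = "synthetic_truth")
}

unit_shape <- function(coords) {
  m <- sweep(coords, 2L, colMeans(coords))
  as.vector(t(m / sqrt(sum(m^2))))
}

# Orthonormal basis (2k x 4) of the similarity null space at a centered
# unit shape: x/y translation, scaling, infinitesimal rotation.
nuisance_basis <- function(shape_vec) {
  k <- length(shape_vec) / 2L
  m <- unflatten_shape(shape_vec)
  tx <- as.vector(t(cbind(rep(1, k), rep(0, k))))
  ty <- as.vector(t(cbind(rep(0, k), rep(1, k))))
  sc <- shape_vec
  rot <- as.vector(t(cbind(-m[, 2L], m[, 1L])))
  qr.Q(qr(cbind(tx, ty, sc, rot)))
}

# Materialize a stage: mean unit shape + allometry + noise, then scaled to
# the requested centroid size.
make_stage_config <- function(truth, deviation, log_cs, specimen_id, taxon,
                              stage) {
  s <- truth$base_shape + deviation +
    (log_cs - truth$log_cs_ref) * truth$allometric_slope * truth$allometric_vector
  if (truth$noise_sd > 0)
    s <- s + stats::rnorm(length(s), sd = truth$noise_sd / sqrt(2))
  m <- unflatten_shape(s)
  m <- m * exp(log_cs) / centroid_size(m)
  landmark_configuration(m, specimen_id = specimen_id, taxon = taxon,
                         stage = stage,
                         is_semilandmark = truth$base$is_semilandmark)
}

#' Simulate one two-stage ontogeny
#'
#' Juvenile and adult configurations of one taxon: each stage's shape is
#' the base shape displaced along the allometric axis by
#' (log CS - reference) times the allometric slope, plus digitization
#' noise; sizes are applied by uniform scaling so the returned
#' configurations have centroid size exp(log CS).
#'
#' @param truth a [synthetic_truth()].
#' @param log_cs_juvenile,log_cs_adult stage log centroid sizes
#'   (adult > juvenile).
#' @param taxon taxon label.
#' @param seed optional seed (defaults to `truth$seed`).
#' @return list with elements `juvenile` and `adult` (`landmark_config`).
#' @export
simulate_ontogeny <- function(truth, log_cs_juvenile = 0.5, log_cs_adult = 2,
                              taxon = "synth", seed = truth$seed) {
  if (log_cs_adult <= log_cs_juvenile)
    stop("adult log CS must exceed juvenile log CS")
  if (!is.null(seed)) { old <- local_seed(seed); on.exit(restore_seed(old)) }
  zero <- numeric(length(truth$base_shape))
  list(juvenile = make_stage_config(truth, zero, log_cs_juvenile,
                                    paste0(taxon, "_juv"), taxon, "juvenile"),
       adult = make_stage_config(truth, zero, log_cs_adult,
                                 paste0(taxon, "_ad"), taxon, "adult"))
}

#' Simulate a clade of ontogenetic series on a time tree
#'
#' Adult mean shapes evolve from the base shape by Brownian motion along
#' the calibrated tree (rate `bm_rate` per coordinate per Myr, increments
#' projected off the similarity null directions); adult log centroid sizes
#' evolve by scalar Brownian motion. Branches named in
#' `truth$heterochrony_shifts` (by tip or internal-node label) receive an
#' additional signed displacement along the allometric axis, inherited by
#' all descendants. Every tip yields an adult configuration; taxa listed
#' in `juvenile_taxa` also yield a juvenile obtained by reversing the
#' lineage's ontogeny along the allometric axis. All specimens carry
#' digitization noise.
#'
#' @param tree a calibrated `time_tree`.
#' @param truth a [synthetic_truth()].
#' @param juvenile_taxa tip labels that preserve a juvenile stage.
#' @param log_cs_adult,log_cs_juvenile stage log centroid sizes before the
#'   size Brownian deviation.
#' @param seed optional seed (defaults to `truth$seed`).
#' @return list with `configs` (juveniles + adults), `truth`,
#'   `adult_means` (noise-free adult mean shape per tip),
#'   `adult_log_cs` (named), `applied_shifts`.
#' @export
simulate_clade <- function(tree, truth, juvenile_taxa = character(0),
                           log_cs_adult = 2, log_cs_juvenile = 0.5,
                           seed = truth$seed) {
  stopifnot(inherits(tree, "time_tree"))
  if (!is.null(seed)) { old <- local_seed(seed); on.exit(restore_seed(old)) }
  phy <- tree$phylo
  n <- length(phy$tip.label)
  p <- length(truth$base_shape)
  Q <- truth$nuisance_basis
  dev <- matrix(0, n + phy$Nnode, p)
  cs_dev <- numeric(n + phy$Nnode)
  labs <- c(phy$tip.label,
            if (!is.null(phy$node.label)) phy$node.label else rep("", phy$Nnode))
  pre <- ape::reorder.phylo(phy, "cladewise")
  shifts <- truth$heterochrony_shifts
  applied <- character(0)
  for (e in seq_len(nrow(pre$edge))) {
    par <- pre$edge[e, 1L]; ch <- pre$edge[e, 2L]
    len <- pre$edge.length[e]
    step <- stats::rnorm(p, sd = sqrt(truth$bm_rate * len))
    step <- step - as.vector(Q %*% crossprod(Q, step))
    dev[ch, ] <- dev[par, ] + step
    cs_dev[ch] <- cs_dev[par] + stats::rnorm(1, sd = sqrt(truth$bm_rate_logcs * len))
    lb <- labs[ch]
    if (nzchar(lb) && lb %in% names(shifts)) {
      dev[ch, ] <- dev[ch, ] + shifts[[lb]] * truth$allometric_vector
      applied <- c(applied, lb)
    }
  }
  configs <- list()
  adult_means <- matrix(0, n, p, dimnames = list(phy$tip.label, NULL))
  adult_lcs <- stats::setNames(log_cs_adult + cs_dev[seq_len(n)], phy$tip.label)
  for (i in seq_len(n)) {
    tip <- phy$tip.label[i]
    adult_means[i, ] <- truth$base_shape + dev[i, ]
    configs[[length(configs) + 1L]] <-
      make_stage_config(truth, dev[i, ], adult_lcs[[tip]],
                        paste0(tip, "_ad"), tip, "adult")
    if (tip %in% juvenile_taxa) {
      configs[[length(configs) + 1L]] <-
        make_stage_config(truth, dev[i, ],
                          log_cs_juvenile + cs_dev[i],
                          paste0(tip, "_juv"), tip, "juvenile")
    }
  }
  list(configs = configs, truth = truth, adult_means = adult_means,
       adult_log_cs = adult_lcs, applied_shifts = applied)
}
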