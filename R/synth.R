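#' Synthetic multi-subject feature datasets
#'
#' Generates per-subject trial x feature matrices with the two statistical
#' properties the cross-subject mapping method assumes: strong
#' class-conditional structure *within* every subject, and subject-specific
#' feature-space geometry so that the class layouts are *misaligned across*
#' subjects. Shared latent class means sit at simplex vertices scaled by
#' `class_separation`; each subject observes them through its own map
#' (random orthogonal rotation by default), plus isotropic Gaussian noise.
#'
#' @param n_subjects number of subjects (default 9).
#' @param n_classes number of stimulus classes (default 6).
#' @param trials_per_class trials per class and subject (default 400, so a
#'   default subject has 2400 trials).
#' @param feature_dim per-subject feature dimension P (default 10).
#' @param latent_dim latent dimension (default `feature_dim`; must be >=
#'   `n_classes` for the simplex construction and <= `feature_dim`).
#' @param class_separation scale of the latent simplex (default 8); with the
#'   default unit noise, class means are separated by `8 * sqrt(2)` noise
#'   standard deviations. `0` removes all class signal.
#' @param noise_sd observation noise standard deviation (default 1).
#' @param subject_map `"orthogonal"` (random rotation, default), `"affine"`
#'   (rotation, per-dimension scaling in \[0.5, 2\] and a shift), or
#'   `"tanh_warp"` (affine followed by a saturating elementwise tanh warp on
#'   a random half of the dimensions).
#' @param seed integer seed; the entire draw is a deterministic function of
#'   it.
#' @return named list of per-subject datasets (`X`, `y`), with attributes
#'   `latent_means` (the shared class means) and `maps` (per-subject map
#'   descriptions).
#' @export
#' @examples
#' d <- synth_features(n_subjects = 2, trials_per_class = 20, seed = 1)
#' dim(d$s1$X)
synth_features <- function(n_subjects = 9, n_classes = 6,
                           trials_per_class = 400, feature_dim = 10,
                           latent_dim = feature_dim, class_separation = 8,
                           noise_sd = 1,
                           subject_map = c("orthogonal", "affine", "tanh_warp"),
                           seed = NULL) {
  subject_map <- match.arg(subject_map)
  if (latent_dim < n_classes)
    stop("latent_dim must be >= n_classes for the simplex construction")
  if (latent_dim > feature_dim)
    stop("latent_dim must be <= feature_dim")
  if (class_separation < 0 || noise_sd <= 0)
    stop("class_separation must be >= 0 and noise_sd > 0")
  if (!is.null(seed)) set.seed(seed)

  # centred simplex vertices in the first n_classes latent coordinates
  mu <- matrix(0, n_classes, latent_dim)
  mu[, seq_len(n_classes)] <- class_separation *
    (diag(n_classes) - 1 / n_classes)

  subjects <- paste0("s", seq_len(n_subjects))
  out <- list()
  maps <- list()
  for (s in subjects) {
    Q <- random_orthogonal(feature_dim)
    map <- list(type = subject_map, Q = Q)
    if (subject_map %in% c("affine", "tanh_warp")) {
      map$scale <- stats::runif(feature_dim, 0.5, 2)
      map$shift <- stats::rnorm(feature_dim, sd = class_separation / 4)
    }
    if (subject_map == "tanh_warp") {
      map$warp_dims <- sample.int(feature_dim, max(1L, feature_dim %/% 2L))
      map$warp_scale <- class_separation / 2
    }
    y <- rep(seq_len(n_classes), each = trials_per_class)
    Z <- mu[y, , drop = FALSE]
    if (latent_dim < feature_dim)
      Z <- cbind(Z, matrix(0, nrow(Z), feature_dim - latent_dim))
    X <- Z %*% t(Q)
    if (subject_map %in% c("affine", "tanh_warp"))
      X <- sweep(sweep(X, 2, map$scale, "*"), 2, map$shift, "+")
    if (subject_map == "tanh_warp") {
      wd <- map$warp_dims
      X[, wd] <- map$warp_scale * tanh(X[, wd] / map$warp_scale)
    }
    X <- X + matrix(stats::rnorm(length(X), sd = noise_sd), nrow(X))
    out[[s]] <- list(X = X, y = as.character(y))
    maps[[s]] <- map
  }
  attr(out, "latent_means") <- mu
  attr(out, "maps") <- maps
  out
}

random_orthogonal <- function(d) {
  qr_d <- qr(matrix(stats::rnorm(d * d), d))
  Q <- qr.Q(qr_d)
  Q %*% diag(sign(diag(qr.R(qr_d))), d)
}

#' Synthetic spike-timing tables
#'
#' Generates raw spike trains over the 10-muscle roster inside a wing-stroke
#' window, with class structure carried by spike *timing*: each (class,
#' muscle) pair has a template set of spike phases; trials jitter the phases
#' with Gaussian noise and drop or add spikes at a low rate; every subject
#' shifts each muscle's phases by its own offset; and a capped number of
#' muscles per subject may be missing entirely.
#'
#' @param n_subjects,n_classes,seed as in [synth_features()].
#' @param trials_per_class trials per class and subject (default 50).
#' @param tau wing-stroke window length in ms (default 60).
#' @param jitter_sd per-spike timing jitter in ms (default 1).
#' @param drop_prob probability of deleting each template spike (default
#'   0.02); the same rate governs spurious spike insertion.
#' @param subject_offset_sd per-subject, per-muscle phase offset sd in ms
#'   (default 2).
#' @param missing_muscle_prob per-muscle probability of being missing in a
#'   subject (default 0), capped at 2 missing muscles per subject.
#' @return data frame with columns `subject_id`, `trial_id`, `label`,
#'   `muscle_id`, `spike_time_ms`, carrying a `missing` attribute (data
#'   frame `subject_id`, `muscle_id`) and a `templates` attribute.
#' @export
synth_spikes <- function(n_subjects = 9, n_classes = 6, trials_per_class = 50,
                         tau = 60, jitter_sd = 1, drop_prob = 0.02,
                         subject_offset_sd = 2, missing_muscle_prob = 0,
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  roster <- muscle_roster()
  # template phases: per muscle a base phase, per class a distinct offset
  # 9 ms apart (>> the 2.5 ms kernel bandwidth), all inside the window
  base <- stats::runif(length(roster), 0, 6)
  templates <- list()
  for (u in seq_along(roster)) {
    for (cl in seq_len(n_classes)) {
      n_sp <- 1L + (u + cl) %% 2L     # 1 or 2 spikes per muscle and class
      ph <- base[u] + (cl - 1) * 9 + c(0, 25)[seq_len(n_sp)]
      templates[[paste(roster[u], cl, sep = ".")]] <- ph[ph <= tau - 2]
    }
  }
  rows <- list(); ri <- 0L
  missing <- data.frame(subject_id = character(), muscle_id = character())
  for (si in seq_len(n_subjects)) {
    s <- paste0("s", si)
    offs <- stats::rnorm(length(roster), sd = subject_offset_sd)
    miss_idx <- which(stats::runif(length(roster)) < missing_muscle_prob)
    if (length(miss_idx) > 2L) miss_idx <- miss_idx[1:2]
    if (length(miss_idx))
      missing <- rbind(missing, data.frame(subject_id = s,
                                           muscle_id = roster[miss_idx]))
    tr <- 0L
    for (cl in seq_len(n_classes)) {
      for (t in seq_len(trials_per_class)) {
        tr <- tr + 1L
        for (u in seq_along(roster)) {
          if (u %in% miss_idx) next
          ph <- templates[[paste(roster[u], cl, sep = ".")]] + offs[u]
          keep <- stats::runif(length(ph)) >= drop_prob
          ph <- ph[keep]
          if (stats::runif(1) < drop_prob)
            ph <- c(ph, stats::runif(1, 0, tau))
          ph <- ph + stats::rnorm(length(ph), sd = jitter_sd)
          ph <- sort(pmin(pmax(ph, 0), tau))
          if (!length(ph)) next
          ri <- ri + 1L
          rows[[ri]] <- data.frame(subject_id = s,
                                   trial_id = sprintf("%s.t%04d", s, tr),
                                   label = as.character(cl),
                                   muscle_id = roster[u],
                                   spike_time_ms = ph)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "missing") <- missing
  attr(out, "templates") <- templates
  out
}
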