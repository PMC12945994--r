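#' Subject layout for a concatenated feature vector
#'
#' Describes how the columns of a concatenated multi-subject visible vector
#' x = (x_1, ..., x_M) split into ordered per-subject blocks, and which
#' subjects currently play the target and source roles. Target and source
#' sets must be disjoint.
#'
#' @param subjects character vector of subject identifiers (ordered as the
#'   blocks are concatenated).
#' @param dims integer vector of per-subject block dimensions, recycled if
#'   scalar.
#' @param targets,sources optional character subsets of `subjects` assigning
#'   roles; may be set later with [set_roles()].
#' @return object of class `subject_layout` with fields `subjects`, `dims`,
#'   `slices` (named list of column index vectors partitioning `1:D`), `D`,
#'   `targets`, `sources`.
#' @export
#' @examples
#' lay <- subject_layout(c("m1", "m2", "m3"), dims = 10)
#' lay$slices$m2
subject_layout <- function(subjects, dims, targets = character(),
                           sources = character()) {
  subjects <- as.character(subjects)
  if (anyDuplicated(subjects)) stop("subject identifiers must be unique")
  dims <- as.integer(rep(dims, length.out = length(subjects)))
  if (any(dims < 1L)) stop("all subject dimensions must be >= 1")
  ends <- cumsum(dims)
  slices <- Map(function(e, d) (e - d + 1L):e, ends, dims)
  names(slices) <- subjects
  lay <- structure(list(subjects = subjects, dims = dims, slices = slices,
                        D = sum(dims), targets = character(),
                        sources = character()),
                   class = "subject_layout")
  if (length(targets) || length(sources)) lay <- set_roles(lay, targets, sources)
  lay
}

#' Assign target and source roles on a layout
#'
#' @param layout a [subject_layout()].
#' @param targets,sources disjoint character subsets of `layout$subjects`.
#' @return the layout with roles set.
#' @export
set_roles <- function(layout, targets, sources) {
  stopifnot(inherits(layout, "subject_layout"))
  targets <- as.character(targets); sources <- as.character(sources)
  unknown <- setdiff(c(targets, sources), layout$subjects)
  if (length(unknown)) stop("unknown subjects: ", paste(unknown, collapse = ", "))
  if (length(intersect(targets, sources)))
    stop("target and source sets must be disjoint")
  layout$targets <- targets
  layout$sources <- sources
  layout
}

#' @export
print.subject_layout <- function(x, ...) {
  cat(sprintf("subject_layout: %d subjects, D = %d\n",
              length(x$subjects), x$D))
  for (s in x$subjects) {
    role <- if (s %in% x$targets) "target"
            else if (s %in% x$sources) "source" else "-"
    cat(sprintf("  %-10s dim %3d cols [%d, %d]  %s\n", s,
                length(x$slices[[s]]), min(x$slices[[s]]),
                max(x$slices[[s]]), role))
  }
  invisible(x)
}

#' Build the concatenated joint training matrix by within-class pairing
#'
#' Trial-level correspondence across subjects is unknown, so joint training
#' rows are assembled by pairing trials at random *within the same stimulus
#' class*: for each class, every subject contributes one trial per joint row,
#' drawn without replacement until that subject's class pool is exhausted and
#' with replacement afterwards. The number of joint rows per class is the
#' largest class count across subjects.
#'
#' @param datasets named list of per-subject feature sets, each a list with
#'   `X` (n x P matrix) and `y` (length-n labels). Names must match
#'   `layout$subjects` when `layout` is given.
#' @param layout optional [subject_layout()]; derived from `datasets` when
#'   missing.
#' @return list with `X` (N x D joint matrix), `y` (length-N class labels)
#'   and `layout`.
#' @export
build_joint_training_set <- function(datasets, layout = NULL) {
  if (is.null(names(datasets)) || any(!nzchar(names(datasets))))
    stop("datasets must be a named list")
  if (is.null(layout)) {
    layout <- subject_layout(names(datasets),
                             vapply(datasets, function(d) ncol(d$X), 0L))
  }
  if (!identical(names(datasets), layout$subjects))
    datasets <- datasets[layout$subjects]
  classes <- sort(unique(unlist(lapply(datasets, function(d) as.character(d$y)))))
  for (s in layout$subjects) {
    miss <- setdiff(classes, as.character(datasets[[s]]$y))
    if (length(miss))
      stop(sprintf("subject '%s' has no trials for class(es): %s", s,
                   paste(miss, collapse = ", ")))
  }
  rows <- list(); labs <- character()
  for (cl in classes) {
    counts <- vapply(datasets,
                     function(d) sum(as.character(d$y) == cl), 0L)
    n_cl <- max(counts)
    blocks <- lapply(layout$subjects, function(s) {
      pool <- which(as.character(datasets[[s]]$y) == cl)
      # without replacement until exhausted, then with replacement
      take <- pool[sample.int(length(pool))]
      if (n_cl > length(pool))
        take <- c(take, sample(pool, n_cl - length(pool), replace = TRUE))
      datasets[[s]]$X[take[seq_len(n_cl)], , drop = FALSE]
    })
    rows[[cl]] <- do.call(cbind, blocks)
    labs <- c(labs, rep(cl, n_cl))
  }
  list(X = do.call(rbind, rows), y = labs, layout = layout)
}

#' Map target-subject features into source feature spaces
#'
#' Implements conditional Gibbs sampling from the fitted joint density: the
#' visible state is initialised with the supplied target features in their
#' blocks and independent standard normal noise everywhere else, then `k`
#' full (hidden, visible) sweeps are run and the source blocks of the final
#' state are returned.
#'
#' @param x_T numeric matrix (n trials x sum of target dims) or vector whose
#'   columns are the concatenation, in layout order, of the feature blocks of
#'   the subjects in `targets`. Blocks of subjects in neither role are
#'   noise-initialised and freely resampled.
#' @param layout a [subject_layout()]; roles are taken from `targets` /
#'   `sources` arguments when given, else from the layout.
#' @param params an [rbm_params] object trained on the same layout.
#' @param k positive integer number of Gibbs sweeps (default 1).
#' @param mode `"mean_readout"` (default): the final visible update is
#'   replaced by the conditional mean \eqn{W^\top h + c}, restricted to the
#'   source blocks (the maximising readout); `"sampled"`: the final visible
#'   state is drawn from \eqn{p(x|h)}.
#' @param clamp `"clamped"` (default): the target blocks are re-imposed after
#'   every visible update, making the chain an exact Gibbs sampler for
#'   \eqn{p(x_{S} | x_{T})}; `"unclamped"`: the full visible vector is
#'   resampled every sweep. For `k = 1` the two produce identical source
#'   outputs under the same seed.
#' @param targets,sources optional role overrides (character subsets of
#'   `layout$subjects`).
#' @return numeric n x (sum of source dims) matrix of mapped features, with
#'   columns in layout order of the source subjects.
#' @export
cross_subject_map <- function(x_T, layout, params, k = 1L,
                              mode = c("mean_readout", "sampled"),
                              clamp = c("clamped", "unclamped"),
                              targets = NULL, sources = NULL) {
  mode <- match.arg(mode)
  clamp <- match.arg(clamp)
  stopifnot(inherits(layout, "subject_layout"))
  if (!is.null(targets) || !is.null(sources))
    layout <- set_roles(layout, targets %||% layout$targets,
                        sources %||% layout$sources)
  if (!length(layout$targets)) stop("layout has no target subjects")
  if (!length(layout$sources)) stop("layout has no source subjects")
  if (layout$D != params$D)
    stop(sprintf("layout dimension %d does not match model D = %d",
                 layout$D, params$D))
  if (!is.matrix(x_T)) x_T <- matrix(x_T, nrow = 1)
  tcols <- unlist(layout$slices[layout$targets], use.names = FALSE)
  scols <- unlist(layout$slices[layout$sources], use.names = FALSE)
  if (ncol(x_T) != length(tcols))
    stop(sprintf("x_T has %d columns but the target blocks span %d",
                 ncol(x_T), length(tcols)))
  if (k < 1 || k != round(k)) stop("k must be a positive integer")
  n <- nrow(x_T)

  xhat <- matrix(stats::rnorm(n * params$D), n, params$D)
  xhat[, tcols] <- x_T
  for (step in seq_len(k)) {
    h <- rbm_sample_hidden(xhat, params)
    if (step == k && mode == "mean_readout") {
      xhat <- h %*% params$W + matrix(params$c, n, params$D, byrow = TRUE)
    } else {
      xhat <- rbm_sample_visible(h, params)
    }
    if (clamp == "clamped") xhat[, tcols] <- x_T
  }
  xhat[, scols, drop = FALSE]
}

#' Cross-subject mapping with a fitted RBM
#'
#' `predict()` on a fitted [gbrbm] model performs the test-time transfer:
#' given feature vectors of target subjects, it returns their representation
#' in the feature spaces of the source subjects, obtained by conditional
#' Gibbs sampling from the fitted joint density (see [cross_subject_map()]).
#'
#' @param object a fitted [gbrbm] with a `layout` (or pass `layout`).
#' @param newdata numeric matrix of target-block features (n x sum of target
#'   dims, in layout order of `targets`).
#' @param targets,sources character subsets of the layout's subjects.
#' @param k,mode,clamp see [cross_subject_map()].
#' @param layout optional layout override.
#' @param seed optional integer seed for the noise initialisation and the
#'   Gibbs draws.
#' @param ... unused.
#' @return numeric n x (sum of source dims) matrix.
#' @export
predict.gbrbm <- function(object, newdata, targets = NULL, sources = NULL,
                          k = 1L, mode = c("mean_readout", "sampled"),
                          clamp = c("clamped", "unclamped"),
                          layout = NULL, seed = NULL, ...) {
  layout <- layout %||% object$layout
  if (is.null(layout)) stop("model has no subject layout; pass `layout`")
  if (!is.null(seed)) set.seed(seed)
  cross_subject_map(newdata, layout, object$params, k = k,
                    mode = match.arg(mode), clamp = match.arg(clamp),
                    targets = targets, sources = sources)
}
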