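#' Train a linear discriminant decoder
#'
#' Linear discriminant analysis (shared within-class covariance, class means,
#' priors from class frequencies), the downstream classifier used for
#' stimulus decoding. Uses [MASS::lda()]; when the pooled covariance is
#' singular (e.g. constant features), falls back to a ridge-regularised
#' Gaussian discriminant with a logged epsilon.
#'
#' @param x numeric n x P feature matrix.
#' @param y length-n class labels (at least two distinct classes).
#' @return object of class `rbm_decoder` supporting `predict(obj, newdata)`,
#'   with fields `engine` (`"lda"` or `"ridge"`), `classes` and (for ridge)
#'   `epsilon`.
#' @export
train_decoder <- function(x, y) {
  x <- as.matrix(x)
  colnames(x) <- paste0("f", seq_len(ncol(x)))
  y <- factor(as.character(y))
  if (nlevels(y) < 2L) stop("need at least two classes to train a decoder")
  fit <- tryCatch(MASS::lda(x, grouping = y),
                  error = function(e) NULL,
                  warning = function(w) NULL)
  if (!is.null(fit)) {
    return(structure(list(engine = "lda", fit = fit, classes = levels(y)),
                     class = "rbm_decoder"))
  }
  # ridge-regularised Gaussian discriminant with pooled covariance
  means <- t(vapply(levels(y), function(cl)
    colMeans(x[y == cl, , drop = FALSE]), numeric(ncol(x))))
  centred <- x - means[as.integer(y), , drop = FALSE]
  S <- crossprod(centred) / max(nrow(x) - nlevels(y), 1L)
  eps <- 1e-6 * max(mean(diag(S)), 1e-12)
  Sinv <- solve(S + diag(eps, ncol(x)))
  structure(list(engine = "ridge", means = means, Sinv = Sinv,
                 priors = as.numeric(table(y)) / length(y),
                 classes = levels(y), epsilon = eps),
            class = "rbm_decoder")
}

#' @export
predict.rbm_decoder <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  colnames(newdata) <- paste0("f", seq_len(ncol(newdata)))
  if (object$engine == "lda") {
    as.character(stats::predict(object$fit, newdata)$class)
  } else {
    disc <- newdata %*% object$Sinv %*% t(object$means)
    disc <- sweep(disc, 2, 0.5 * rowSums(object$means *
                                           (object$means %*% object$Sinv)), "-")
    disc <- sweep(disc, 2, log(object$priors), "+")
    object$classes[max.col(disc, ties.method = "first")]
  }
}

#' @export
print.rbm_decoder <- function(x, ...) {
  cat(sprintf("linear discriminant decoder (%s engine), %d classes\n",
              x$engine, length(x$classes)))
  invisible(x)
}

decode_accuracy <- function(decoder, x, y) {
  mean(predict(decoder, x) == as.character(y))
}

# stratified train/test split: per class, a fraction omega goes to training
stratified_split <- function(y, omega) {
  y <- as.character(y)
  train <- logical(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    n_tr <- max(1L, round(omega * length(idx)))
    n_tr <- min(n_tr, length(idx) - 1L)
    train[sample(idx, n_tr)] <- TRUE
  }
  train
}

#' Run a cross-subject decoding scenario
#'
#' Repeated-random-split evaluation of cross-subject decoding. Per repeat:
#' every subject's trials are split into training and test halves (ratio
#' `omega`, stratified by class); features are z-scored per subject with
#' training-split statistics; decoders are trained per subject on training
#' halves; one joint RBM per requested training method is fitted on the
#' within-class-paired concatenation of the training halves; and each
#' requested method is scored on test trials:
#' \describe{
#'   \item{subject_specific}{decoder trained and tested on the same
#'     subject's split (upper-bound benchmark).}
#'   \item{no_transfer}{the source decoder applied directly to raw target
#'     test features (chance-level benchmark).}
#'   \item{rbm_fd / rbm_cd}{target test features mapped into the source
#'     space by conditional Gibbs sampling from the fitted RBM, then decoded
#'     by the source decoder.}
#'   \item{external}{an optional plug-in alignment benchmark; see
#'     `external`.}
#' }
#' In scenario `"I"` the fixed `subject` is the single source and every other
#' subject is a target; in scenario `"II"` it is the single target and is
#' decoded in every other subject's feature space by that subject's decoder.
#'
#' @param scenario `"I"` or `"II"`.
#' @param subject subject identifier: the source (scenario I) or target
#'   (scenario II).
#' @param datasets named list of per-subject feature datasets (`X`, `y`).
#' @param methods character subset of `c("subject_specific", "no_transfer",
#'   "rbm_fd", "rbm_cd", "external")`.
#' @param omega train fraction of the split (default 0.5).
#' @param repeats number of random splits (default 100).
#' @param hidden,epochs,learning_rate,batch_size,k_cd RBM hyperparameters
#'   passed to [gbrbm()]; `batch_size` is capped at the joint training size.
#' @param k,mode Gibbs mapping parameters passed to [predict.gbrbm()].
#' @param standardize z-score features per subject with training-split
#'   statistics before RBM training and decoding (default FALSE). Mapping
#'   initialises unknown blocks with standard normal noise, so features are
#'   deliberately kept on their natural (larger) scale by default; see the
#'   package vignette.
#' @param external optional function `(x_src_train, y_src_train,
#'   x_tgt_train, y_tgt_train) -> function(x_tgt) -> x_in_src_space`
#'   registering an external alignment method (e.g. a hierarchical
#'   Wasserstein alignment implementation) as a benchmark.
#' @param seed master seed; per-repeat seeds are derived from it.
#' @return data frame of class `eval_report` with columns `scenario`,
#'   `method`, `source`, `target`, `rep` and `accuracy` (one row per
#'   evaluated source/target pair and repeat).
#' @export
run_scenario <- function(scenario = c("I", "II"), subject, datasets,
                         methods = c("subject_specific", "no_transfer",
                                     "rbm_fd"),
                         omega = 0.5, repeats = 100L, hidden = 15L,
                         epochs = 350L, learning_rate = 0.005,
                         batch_size = 150L, k_cd = 1L, k = 1L,
                         mode = "mean_readout", standardize = FALSE,
                         external = NULL, seed = NULL) {
  scenario <- match.arg(scenario)
  subjects <- names(datasets)
  if (length(subjects) < 2L) stop("need at least two subjects")
  if (!subject %in% subjects) stop("unknown subject: ", subject)
  methods <- match.arg(methods, c("subject_specific", "no_transfer",
                                  "rbm_fd", "rbm_cd", "external"),
                       several.ok = TRUE)
  if ("external" %in% methods && is.null(external))
    stop("method 'external' requested but no external aligner was supplied")
  rbm_methods <- intersect(methods, c("rbm_fd", "rbm_cd"))
  seeds <- derive_seeds(seed %||% sample.int(1e6, 1), repeats)
  P <- ncol(datasets[[1]]$X)
  layout <- subject_layout(subjects, dims = vapply(datasets,
                                                   function(d) ncol(d$X), 0L))
  others <- setdiff(subjects, subject)
  res <- list()

  for (r in seq_len(repeats)) {
    set.seed(seeds[r])
    tr <- list(); te <- list()
    for (s in subjects) {
      d <- datasets[[s]]
      is_tr <- stratified_split(d$y, omega)
      Xtr <- d$X[is_tr, , drop = FALSE]; Xte <- d$X[!is_tr, , drop = FALSE]
      if (standardize) {
        zs <- zscore_fit(Xtr)
        Xtr <- zscore_apply(Xtr, zs); Xte <- zscore_apply(Xte, zs)
      }
      tr[[s]] <- list(X = Xtr, y = d$y[is_tr])
      te[[s]] <- list(X = Xte, y = d$y[!is_tr])
    }
    decoders <- lapply(tr, function(d) train_decoder(d$X, d$y))

    fits <- list()
    if (length(rbm_methods)) {
      joint <- build_joint_training_set(tr, layout)
      for (m in rbm_methods) {
        fits[[m]] <- gbrbm(joint$X, hidden = hidden,
                           method = if (m == "rbm_fd") "fd" else "cd",
                           epochs = epochs, learning_rate = learning_rate,
                           batch_size = min(batch_size, nrow(joint$X)),
                           k_cd = k_cd, layout = layout,
                           trace_every = max(1L, epochs))
      }
    }

    add <- function(method, src, tgt, acc) {
      res[[length(res) + 1L]] <<- data.frame(
        scenario = scenario, method = method, source = src, target = tgt,
        rep = r, accuracy = acc)
    }

    if (scenario == "I") {
      src <- subject
      for (tgt in others) {
        if ("subject_specific" %in% methods)
          add("subject_specific", src, tgt,
              decode_accuracy(decoders[[tgt]], te[[tgt]]$X, te[[tgt]]$y))
        if ("no_transfer" %in% methods)
          add("no_transfer", src, tgt,
              decode_accuracy(decoders[[src]], te[[tgt]]$X, te[[tgt]]$y))
        for (m in rbm_methods) {
          mapped <- predict(fits[[m]], te[[tgt]]$X, targets = tgt,
                            sources = src, k = k, mode = mode)
          add(m, src, tgt,
              mean(predict(decoders[[src]], mapped) ==
                     as.character(te[[tgt]]$y)))
        }
        if ("external" %in% methods) {
          transform <- external(tr[[src]]$X, tr[[src]]$y,
                                tr[[tgt]]$X, tr[[tgt]]$y)
          add("external", src, tgt,
              mean(predict(decoders[[src]], transform(te[[tgt]]$X)) ==
                     as.character(te[[tgt]]$y)))
        }
      }
    } else {
      tgt <- subject
      mapped_all <- list()
      for (m in rbm_methods) {
        mapped_all[[m]] <- predict(fits[[m]], te[[tgt]]$X, targets = tgt,
                                   sources = others, k = k, mode = mode)
      }
      col0 <- 0L
      for (src in others) {
        if ("subject_specific" %in% methods)
          add("subject_specific", src, tgt,
              decode_accuracy(decoders[[src]], te[[src]]$X, te[[src]]$y))
        if ("no_transfer" %in% methods)
          add("no_transfer", src, tgt,
              decode_accuracy(decoders[[src]], te[[tgt]]$X, te[[tgt]]$y))
        for (m in rbm_methods) {
          block <- mapped_all[[m]][, col0 + seq_len(P), drop = FALSE]
          add(m, src, tgt,
              mean(predict(decoders[[src]], block) ==
                     as.character(te[[tgt]]$y)))
        }
        if ("external" %in% methods) {
          transform <- external(tr[[src]]$X, tr[[src]]$y,
                                tr[[tgt]]$X, tr[[tgt]]$y)
          add("external", src, tgt,
              mean(predict(decoders[[src]], transform(te[[tgt]]$X)) ==
                     as.character(te[[tgt]]$y)))
        }
        col0 <- col0 + P
      }
    }
  }
  out <- do.call(rbind, res)
  class(out) <- c("eval_report", class(out))
  out
}

#' Summarise an evaluation report
#'
#' Aggregates per-repeat accuracies into mean and 95% percentile confidence
#' intervals (2.5 and 97.5 percentiles over repeats).
#'
#' @param report an `eval_report` from [run_scenario()] (or any data frame
#'   with the same columns).
#' @param by grouping columns (default `c("scenario", "method", "source",
#'   "target")`); use `c("scenario", "method")` to pool over subjects.
#' @return data frame with columns `by`, `n_rep`, `mean`, `ci_low`,
#'   `ci_high`.
#' @export
summarize_report <- function(report,
                             by = c("scenario", "method", "source",
                                    "target")) {
  if (nrow(report) == 0L)
    return(data.frame(matrix(nrow = 0, ncol = length(by) + 4,
                             dimnames = list(NULL, c(by, "n_rep", "mean",
                                                     "ci_low", "ci_high")))))
  key <- interaction(report[by], drop = TRUE, sep = "\r")
  agg <- lapply(split(report, key), function(g) {
    cbind(g[1, by, drop = FALSE],
          data.frame(n_rep = length(unique(g$rep)),
                     mean = mean(g$accuracy),
                     ci_low = unname(stats::quantile(g$accuracy, 0.025)),
                     ci_high = unname(stats::quantile(g$accuracy, 0.975))))
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out
}
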