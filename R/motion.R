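# Inference layer: frame averaging, PCA calibration/projection for motion
# separation, multicoil least-squares regression against reference traces,
# separating-plane computation, and MIMO (multi-antenna) channel stacking.

#' Frame-average an extracted tone series
#'
#' Averages |value| of a `bpt_series` within each frame, yielding a
#' frames x channels matrix - the preprocessing step before PCA when tone
#' data are acquired many lines per image frame.
#'
#' @param series A `bpt_series` (see [extract_tone()]).
#' @param frame_boundaries Increasing vector of frame edges in line index
#'   units (length `n_frames + 1`); frame k covers lines in
#'   `[b[k], b[k+1])`.
#' @param labels Optional label per frame.
#' @param antenna_id Optional antenna identifier for the whole channel block.
#' @return A `bpt_frames` object: list with `matrix` (frames x channels),
#'   `frame_times`, `labels`, `antenna_id`.
#' @export
frame_average <- function(series, frame_boundaries, labels = NULL,
                          antenna_id = NULL) {
  if (any(diff(frame_boundaries) <= 0)) {
    stop("frame boundaries must be strictly increasing")
  }
  m <- series_matrix(series, value = "magnitude")
  tms <- sort(unique(series$line_time_s))
  nf <- length(frame_boundaries) - 1
  out <- matrix(0, nf, ncol(m))
  ft <- numeric(nf)
  for (k in seq_len(nf)) {
    idx <- which(seq_len(nrow(m)) >= frame_boundaries[k] &
                   seq_len(nrow(m)) < frame_boundaries[k + 1])
    if (length(idx) == 0) stop("empty frame in frame_average")
    out[k, ] <- colMeans(m[idx, , drop = FALSE])
    ft[k] <- mean(tms[idx])
  }
  new_frames(out, frame_times = ft, labels = labels, antenna_id = antenna_id)
}

#' Construct a labelled frame set
#'
#' @param matrix Numeric matrix, frames x channels.
#' @param frame_times Optional frame time stamps (s).
#' @param labels Optional label per frame (e.g. "nod"/"shake").
#' @param antenna_id Antenna identifier per channel (recycled if scalar).
#' @return A `bpt_frames` object.
#' @export
new_frames <- function(matrix, frame_times = NULL, labels = NULL,
                       antenna_id = NULL) {
  matrix <- as.matrix(matrix)
  if (!is.null(labels) && length(labels) != nrow(matrix)) {
    stop("one label per frame is required")
  }
  if (!is.null(antenna_id)) {
    antenna_id <- rep(antenna_id, length.out = ncol(matrix))
  }
  structure(list(matrix = matrix,
                 frame_times = frame_times %||% seq_len(nrow(matrix)),
                 labels = labels, antenna_id = antenna_id),
            class = "bpt_frames")
}

#' @export
print.bpt_frames <- function(x, ...) {
  cat(sprintf("<bpt_frames> %d frames x %d channels%s\n",
              nrow(x$matrix), ncol(x$matrix),
              if (!is.null(x$antenna_id))
                sprintf(" (%d antennas)", length(unique(x$antenna_id)))
              else ""))
  invisible(x)
}

#' Stack frame sets from multiple antennas (MIMO)
#'
#' Concatenates the channel blocks of per-antenna frame sets - e.g. a
#' `115 x 22` set per antenna becomes `115 x 44` - keeping antenna
#' bookkeeping so blocks can be recovered exactly with [mimo_split()].
#'
#' @param framesets A list of `bpt_frames` with identical frame axes.
#' @return A single `bpt_frames`.
#' @export
mimo_stack <- function(framesets) {
  nf <- unique(purrr::map_int(framesets, ~ nrow(.x$matrix)))
  if (length(nf) != 1) stop("frame axes do not match across antennas")
  ids <- purrr::imap(framesets, function(fs, i) {
    rep(fs$antenna_id[1] %||% i, ncol(fs$matrix))
  })
  new_frames(do.call(cbind, purrr::map(framesets, "matrix")),
             frame_times = framesets[[1]]$frame_times,
             labels = framesets[[1]]$labels,
             antenna_id = unlist(ids))
}

#' @rdname mimo_stack
#' @param frames A stacked `bpt_frames`.
#' @return For `mimo_split()`: a named list of per-antenna `bpt_frames`.
#' @export
mimo_split <- function(frames) {
  if (is.null(frames$antenna_id)) stop("no antenna bookkeeping present")
  ids <- unique(frames$antenna_id)
  purrr::set_names(purrr::map(ids, function(a) {
    sel <- frames$antenna_id == a
    new_frames(frames$matrix[, sel, drop = FALSE],
               frame_times = frames$frame_times, labels = frames$labels,
               antenna_id = frames$antenna_id[sel])
  }), as.character(ids))
}

# ---- PCA --------------------------------------------------------------------

#' Fit a principal-component model to frame data
#'
#' Mean-centred PCA of a frames x channels matrix with a deterministic sign
#' convention (the largest-|loading| entry of each component is positive).
#' Used to compress calibration data to a few components; new data are then
#' projected with [pca_project()].
#'
#' @param frames A `bpt_frames` or numeric matrix (frames x channels).
#' @param n_pc Number of components to keep.
#' @return A `bpt_pca` object: `means`, `components` (n_pc x channels,
#'   orthonormal rows), `explained` (fraction of variance per component),
#'   `scores` (training scores).
#' @export
pca_fit <- function(frames, n_pc = 3) {
  m <- if (inherits(frames, "bpt_frames")) frames$matrix else as.matrix(frames)
  if (nrow(m) < 2) stop("at least 2 frames are required")
  if (n_pc > min(nrow(m) - 1, ncol(m))) {
    stop("n_pc exceeds min(frames - 1, channels)")
  }
  pc <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  rot <- t(pc$rotation[, seq_len(n_pc), drop = FALSE])   # n_pc x channels
  dimnames(rot) <- NULL
  # sign convention: largest-|loading| entry positive
  for (k in seq_len(n_pc)) {
    j <- which.max(abs(rot[k, ]))
    if (rot[k, j] < 0) rot[k, ] <- -rot[k, ]
  }
  varfrac <- pc$sdev^2 / sum(pc$sdev^2)
  fit <- structure(
    list(means = pc$center, components = rot,
         explained = varfrac[seq_len(n_pc)],
         explained_all = varfrac),
    class = "bpt_pca")
  names(fit$means) <- NULL
  fit$scores <- pca_project(fit, m)
  fit
}

#' Project frames onto a learned principal-component basis
#'
#' @param model A `bpt_pca` from [pca_fit()].
#' @param new_frames A `bpt_frames` or matrix with the same channel count.
#' @return A numeric score matrix, frames x n_pc.
#' @export
pca_project <- function(model, new_frames) {
  m <- if (inherits(new_frames, "bpt_frames")) new_frames$matrix else
    as.matrix(new_frames)
  if (ncol(m) != length(model$means)) {
    stop("channel count does not match the fitted model")
  }
  sweep(m, 2, model$means) %*% t(model$components)
}

#' @export
print.bpt_pca <- function(x, ...) {
  cat(sprintf("<bpt_pca> %d components over %d channels; explained: %s\n",
              nrow(x$components), ncol(x$components),
              paste(sprintf("%.1f%%", 100 * x$explained), collapse = ", ")))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a principal-component model
#'
#' One row per (component, channel) loading.
#' @param x A `bpt_pca`. @param ... Unused.
#' @export
tidy.bpt_pca <- function(x, ...) {
  nc <- ncol(x$components)
  tibble::tibble(
    component = rep(seq_len(nrow(x$components)), each = nc),
    channel = rep(seq_len(nc), times = nrow(x$components)),
    loading = as.vector(t(x$components)))
}

#' @rdname tidy.bpt_pca
#' @export
glance.bpt_pca <- function(x, ...) {
  tibble::tibble(n_pc = nrow(x$components),
                 n_channels = ncol(x$components),
                 explained_fraction = sum(x$explained))
}

# ---- Regression -------------------------------------------------------------

#' Regress multicoil signals to a reference motion trace
#'
#' Ordinary least squares of a de-meaned target on de-meaned channel data
#' (all signals de-meaned before the regression), reporting the Pearson
#' correlation between the fitted combination and the target - the headline
#' accuracy statistic when comparing a tone-derived signal against dBCG or
#' registration-derived components. An optional ridge penalty stabilises
#' ill-conditioned channel sets.
#'
#' @param frames A `bpt_frames`, `bpt_series`, or numeric matrix
#'   (samples x channels).
#' @param target Numeric reference trace, one value per frame/sample.
#' @param ridge Ridge penalty `lambda >= 0` (default 0: pure OLS).
#' @return A `bpt_regression`: `weights`, `intercept`, `fitted`,
#'   `pearson_r`, `target`.
#' @export
regress_multicoil <- function(frames, target, ridge = 0) {
  m <- if (inherits(frames, "bpt_frames")) frames$matrix
  else if (inherits(frames, "bpt_series")) series_matrix(frames, "magnitude")
  else as.matrix(frames)
  if (length(target) != nrow(m)) stop("target length must equal frames")
  if (stats::sd(target) == 0) stop("target has zero variance")
  Xc <- sweep(m, 2, colMeans(m))
  yc <- target - mean(target)
  if (ridge > 0) {
    w <- solve(crossprod(Xc) + ridge * diag(ncol(Xc)), crossprod(Xc, yc))
  } else {
    qx <- qr(Xc)
    if (qx$rank < ncol(Xc)) {
      w <- pracma::pinv(Xc) %*% yc
    } else {
      w <- qr.coef(qx, yc)
    }
  }
  w <- as.numeric(w)
  fitted <- as.numeric(Xc %*% w) + mean(target)
  r <- stats::cor(fitted, target)
  structure(list(weights = w, intercept = mean(target), fitted = fitted,
                 pearson_r = r, target = target),
            class = "bpt_regression")
}

#' @export
print.bpt_regression <- function(x, ...) {
  cat(sprintf("<bpt_regression> %d channels, Pearson r = %.3f\n",
              length(x$weights), x$pearson_r))
  invisible(x)
}

#' Tidy a multicoil regression fit
#' @param x A `bpt_regression`. @param ... Unused.
#' @export
tidy.bpt_regression <- function(x, ...) {
  tibble::tibble(channel = seq_along(x$weights), weight = x$weights)
}

#' @rdname tidy.bpt_regression
#' @export
glance.bpt_regression <- function(x, ...) {
  tibble::tibble(n_channels = length(x$weights),
                 pearson_r = x$pearson_r,
                 r_squared = x$pearson_r^2)
}

# ---- Separating plane -------------------------------------------------------

#' Separating plane between two motion classes in score space
#'
#' Computes a linear separator between two labelled point clouds (e.g.
#' breathing vs bulk-motion frames in PC space). If the classes are
#' linearly separable, a maximum-margin separator is returned (margin > 0);
#' otherwise a least-squares discriminant with margin 0. Leave-one-out
#' accuracy is the reported separability score.
#'
#' @param scores Numeric matrix, points x dimensions.
#' @param labels Factor/character/logical with exactly two classes.
#' @param loo Compute leave-one-out accuracy (default TRUE).
#' @return A `bpt_plane`: unit `normal`, `offset` (plane is
#'   `normal . x + offset = 0`), `margin`, `separable`, `accuracy`
#'   (training), `loo_accuracy`.
#' @export
separability_plane <- function(scores, labels, loo = TRUE) {
  scores <- as.matrix(scores)
  labels <- as.factor(labels)
  if (nlevels(labels) != 2) stop("exactly 2 label classes are required")
  if (min(table(labels)) < 2) stop("each class needs at least 2 points")
  fit <- plane_fit(scores, labels)
  loo_acc <- NA_real_
  if (loo) {
    n <- nrow(scores)
    ok <- logical(n)
    for (i in seq_len(n)) {
      if (min(table(labels[-i])) < 1) { ok[i] <- NA; next }
      f <- plane_fit(scores[-i, , drop = FALSE], labels[-i])
      ok[i] <- identical(plane_classify(f, scores[i, , drop = FALSE]),
                         as.character(labels[i]))
    }
    loo_acc <- mean(ok, na.rm = TRUE)
  }
  structure(c(fit, list(loo_accuracy = loo_acc)), class = "bpt_plane")
}

# hard-margin attempt via a linear SVM with a large cost (large enough that
# support multipliers stay uncapped on separable data, small enough that the
# solver converges quickly when the classes overlap); if training accuracy is
# not perfect, fall back to a least-squares discriminant
plane_fit <- function(scores, labels) {
  y <- ifelse(labels == levels(labels)[1], -1, 1)
  sv <- try(e1071::svm(x = scores, y = as.factor(y), kernel = "linear",
                       cost = 1e3, scale = FALSE), silent = TRUE)
  if (!inherits(sv, "try-error")) {
    w <- as.numeric(t(sv$coefs) %*% sv$SV)
    b <- -sv$rho
    nw <- sqrt(sum(w^2))
    if (nw > 0) {
      pred <- sign(scores %*% w + b)
      # svm labels may be flipped relative to y; align by training agreement
      agree <- mean(pred == y)
      if (agree < 0.5) { w <- -w; b <- -b; pred <- -pred }
      acc <- mean(sign(scores %*% w + b) == y)
      if (acc == 1) {
        margin <- min(abs(scores %*% w + b)) / nw
        return(list(normal = w / nw, offset = b / nw, margin = margin,
                    separable = TRUE, accuracy = 1,
                    levels = levels(labels)))
      }
    }
  }
  # least-squares discriminant: regress +/-1 labels on the scores
  X <- cbind(1, scores)
  beta <- as.numeric(pracma::pinv(X) %*% y)
  w <- beta[-1]; b <- beta[1]
  nw <- sqrt(sum(w^2))
  if (nw == 0) nw <- 1
  acc <- mean(sign(X %*% beta) == y)
  list(normal = w / nw, offset = b / nw, margin = 0, separable = FALSE,
       accuracy = acc, levels = levels(labels))
}

plane_classify <- function(fit, x) {
  s <- as.numeric(as.matrix(x) %*% fit$normal + fit$offset)
  ifelse(s < 0, fit$levels[1], fit$levels[2])
}

#' @export
print.bpt_plane <- function(x, ...) {
  cat(sprintf(
    "<bpt_plane> %s (margin %.3g), training accuracy %.2f, LOO accuracy %s\n",
    if (x$separable) "separable" else "not separable",
    x$margin, x$accuracy,
    ifelse(is.na(x$loo_accuracy), "NA", sprintf("%.2f", x$loo_accuracy))))
  invisible(x)
}

#' @rdname tidy.bpt_pca
#' @export
glance.bpt_plane <- function(x, ...) {
  tibble::tibble(separable = x$separable, margin = x$margin,
                 accuracy = x$accuracy, loo_accuracy = x$loo_accuracy)
}
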