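# Resting-state EEG microstate pipeline: global field power, GFP-peak
# picking, polarity-invariant modified k-means clustering into prototype
# classes, back-fitting, and per-class duration / occurrence / coverage
# statistics. All topographic operations are performed on average-referenced
# data: GFP and polarity-invariant spatial correlation presuppose it.

#' Average-reference a recording
#'
#' Subtracts the instantaneous mean across channels from every sample.
#'
#' @param rec a [recording()].
#' @return the re-referenced `recording`.
#' @export
average_reference <- function(rec) {
  stopifnot(inherits(rec, "recording"))
  rec$data <- sweep(rec$data, 2, colMeans(rec$data))
  rec
}

#' Global field power
#'
#' Per-sample spatial standard deviation across channels (population form:
#' the root-mean-square deviation from the instantaneous channel mean).
#'
#' @param rec a [recording()] with >= 2 channels.
#' @param apply_average_reference re-reference first (default `TRUE`).
#' @return numeric vector, one value per sample.
#' @export
gfp <- function(rec, apply_average_reference = TRUE) {
  stopifnot(inherits(rec, "recording"))
  if (nchannels(rec) < 2) stop("GFP requires at least 2 channels")
  if (apply_average_reference) rec <- average_reference(rec)
  sqrt(colMeans(rec$data^2) - colMeans(rec$data)^2)
}

#' Find GFP peaks
#'
#' Strict local maxima of the GFP series, greedily thinned so that no two
#' kept peaks are closer than `min_separation` samples, keeping the highest
#' first.
#'
#' @param g numeric GFP series (length >= 3).
#' @param min_separation minimal distance between kept peaks, in samples.
#' @return integer vector of peak indices (possibly empty), sorted.
#' @export
find_gfp_peaks <- function(g, min_separation = 1) {
  if (length(g) < 3) stop("series too short for peak picking")
  n <- length(g)
  idx <- which(g[2:(n - 1)] > g[1:(n - 2)] & g[2:(n - 1)] > g[3:n]) + 1L
  if (!length(idx) || min_separation <= 1) return(idx)
  idx <- idx[order(g[idx], decreasing = TRUE)]
  kept <- integer(0)
  for (i in idx)
    if (!length(kept) || all(abs(kept - i) >= min_separation))
      kept <- c(kept, i)
  sort(kept)
}

# GEV of an assignment: sum over maps of the squared projection onto the
# assigned unit prototype, over total map energy (equals the GFP^2-weighted
# squared spatial correlation for zero-mean maps)
.gev <- function(maps, prototypes, assign) {
  proj <- colSums(maps * prototypes[, assign, drop = FALSE])^2
  sum(proj) / sum(maps^2)
}

#' Cluster topographies into prototype classes (modified k-means)
#'
#' Polarity-invariant k-means: maps are assigned to the prototype with the
#' largest squared projection (sign ignored) and each prototype is updated to
#' the first principal component of its assigned maps, which maximizes the
#' global explained variance (GEV). GEV is non-decreasing across iterations;
#' the best of `n_restarts` random restarts is kept.
#'
#' Class letters: when `templates` are supplied (channels x k matrix),
#' clusters are labeled by greedy maximal absolute spatial correlation with
#' the template maps; otherwise letters are assigned in order of decreasing
#' explained variance.
#'
#' @param maps channels x n numeric matrix of (peak) topographies.
#' @param k number of classes (default 4).
#' @param n_restarts random restarts (default 100).
#' @param seed RNG seed.
#' @param templates optional channels x k template maps for letter
#'   assignment.
#' @param max_iter per-restart iteration cap.
#' @param tol convergence threshold on the GEV increment (default 1e-6).
#' @return object of class `microstate_model`: unit-norm `prototypes`
#'   (channels x k, columns named A, B, ...), `gev`, `assign` for the input
#'   maps, and the per-iteration `gev_trace` of the winning restart.
#' @export
cluster_topographies <- function(maps, k = 4, n_restarts = 100, seed = 1,
                                 templates = NULL, max_iter = 100,
                                 tol = 1e-6) {
  maps <- as.matrix(maps)
  n <- ncol(maps)
  if (n < k) stop(sprintf("need at least k = %d maps, got %d", k, n))
  maps <- sweep(maps, 2, colMeans(maps))      # average reference per map
  set.seed(seed)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    proto <- maps[, sample.int(n, k), drop = FALSE]
    proto <- sweep(proto, 2, sqrt(colSums(proto^2)), "/")
    gev_trace <- numeric(0)
    last <- -Inf
    for (it in seq_len(max_iter)) {
      sim <- crossprod(proto, maps)^2         # k x n squared projections
      assign <- max.col(t(sim))
      for (j in seq_len(k)) {
        mj <- maps[, assign == j, drop = FALSE]
        if (!ncol(mj)) next                   # empty class keeps its prototype
        ev <- eigen(tcrossprod(mj), symmetric = TRUE)
        proto[, j] <- ev$vectors[, 1]
      }
      g <- .gev(maps, proto, assign)
      gev_trace <- c(gev_trace, g)
      if (g - last < tol) break
      last <- g
    }
    if (is.null(best) || g > best$gev)
      best <- list(prototypes = proto, gev = g, assign = assign,
                   gev_trace = gev_trace)
  }
  proto <- best$prototypes
  if (!is.null(templates)) {
    templates <- as.matrix(templates)
    if (nrow(templates) != nrow(proto) || ncol(templates) != k)
      stop("templates must be channels x k")
    cors <- abs(stats::cor(proto, templates))   # cluster x template
    ord <- integer(k)
    for (step in seq_len(k)) {
      i <- which(cors == max(cors), arr.ind = TRUE)[1, ]
      ord[i[2]] <- i[1]                         # template letter gets cluster
      cors[i[1], ] <- -Inf; cors[, i[2]] <- -Inf
    }
  } else {
    expl <- vapply(seq_len(k), function(j) {
      sel <- best$assign == j
      if (!any(sel)) 0 else sum(colSums(maps[, sel, drop = FALSE] * proto[, j])^2)
    }, numeric(1))
    ord <- order(expl, decreasing = TRUE)
  }
  proto <- proto[, ord, drop = FALSE]
  colnames(proto) <- LETTERS[seq_len(k)]
  relabel <- match(seq_len(k), ord)
  structure(list(prototypes = proto, gev = best$gev,
                 assign = LETTERS[relabel[best$assign]],
                 gev_trace = best$gev_trace, k = k),
            class = "microstate_model")
}

#' @export
print.microstate_model <- function(x, ...) {
  cat(sprintf("<microstate_model> %d classes (%s), %d channels, GEV = %.3f\n",
              x$k, paste(colnames(x$prototypes), collapse = ""),
              nrow(x$prototypes), x$gev))
  invisible(x)
}

#' Back-fit prototypes to continuous EEG
#'
#' Labels every sample by the prototype with the maximal absolute spatial
#' correlation (polarity-invariant), after average-referencing. An optional
#' majority-vote temporal smoothing window is available but off by default.
#'
#' @param rec a [recording()].
#' @param model a `microstate_model` (or a channels x k prototype matrix).
#' @param smooth_window odd window length in samples for majority smoothing;
#'   0 (default) disables it.
#' @return character vector of class letters, one per sample.
#' @export
backfit <- function(rec, model, smooth_window = 0) {
  proto <- if (inherits(model, "microstate_model")) model$prototypes
           else as.matrix(model)
  stopifnot(inherits(rec, "recording"))
  if (nrow(proto) != nchannels(rec))
    stop(sprintf("channel mismatch: %d prototype rows vs %d recording channels",
                 nrow(proto), nchannels(rec)))
  x <- average_reference(rec)$data
  pz <- sweep(proto, 2, colMeans(proto))
  pz <- sweep(pz, 2, sqrt(colSums(pz^2)), "/")
  sim <- abs(crossprod(pz, x))                # |projection|, rank-equal to |cor|
  lab <- max.col(t(sim), ties.method = "first")
  if (smooth_window > 1) {
    half <- smooth_window %/% 2
    n <- length(lab)
    sm <- lab
    for (i in seq_len(n)) {
      w <- lab[max(1, i - half):min(n, i + half)]
      sm[i] <- as.integer(names(which.max(table(w))))
    }
    lab <- sm
  }
  cn <- colnames(proto)
  if (is.null(cn)) cn <- LETTERS[seq_len(ncol(proto))]
  cn[lab]
}

#' Microstate duration / occurrence / coverage statistics
#'
#' Run-length statistics of a label sequence: per class, the mean instance
#' duration in ms, the occurrence rate in instances per second, and the
#' coverage fraction of samples.
#'
#' @param labels character (or factor) label sequence.
#' @param fs sampling rate (Hz).
#' @return object of class `microstate_stats`: a data.frame with one row per
#'   class and columns `class`, `duration_ms`, `occurrence_per_s`,
#'   `coverage`.
#' @export
microstate_stats <- function(labels, fs) {
  labels <- as.character(labels)
  if (!length(labels)) stop("empty label sequence")
  r <- rle(labels)
  total_s <- length(labels) / fs
  classes <- sort(unique(labels))
  df <- do.call(rbind, lapply(classes, function(cl) {
    runs <- r$lengths[r$values == cl]
    data.frame(class = cl,
               duration_ms = mean(runs) / fs * 1000,
               occurrence_per_s = length(runs) / total_s,
               coverage = sum(runs) / length(labels))
  }))
  rownames(df) <- NULL
  class(df) <- c("microstate_stats", "data.frame")
  df
}

#' Match two label sequences up to class permutation
#'
#' Greedy best-overlap matching of class letters; used to score recovery of
#' a known state sequence.
#'
#' @param est,truth label sequences of equal length.
#' @return agreement fraction in `[0, 1]` after the optimal greedy
#'   relabeling.
#' @export
label_agreement <- function(est, truth) {
  est <- as.character(est); truth <- as.character(truth)
  stopifnot(length(est) == length(truth))
  tab <- table(est, truth)
  agree <- 0
  while (length(tab) && nrow(tab) && ncol(tab)) {
    i <- which(tab == max(tab), arr.ind = TRUE)[1, ]
    agree <- agree + tab[i[1], i[2]]
    tab <- tab[-i[1], -i[2], drop = FALSE]
  }
  agree / length(est)
}

#' Full microstate segmentation pipeline
#'
#' GFP -> peak picking -> modified k-means on peak topographies ->
#' back-fitting -> run-length statistics.
#'
#' @param rec a [recording()].
#' @param k number of classes (default 4).
#' @param n_restarts k-means restarts (default 100).
#' @param seed RNG seed.
#' @param min_peak_separation GFP peak thinning distance in samples.
#' @param templates optional template maps for letter assignment.
#' @return list with `model` (a `microstate_model`), `labels`, and `stats`
#'   (a `microstate_stats` table).
#' @export
microstate_pipeline <- function(rec, k = 4, n_restarts = 100, seed = 1,
                                min_peak_separation = 1, templates = NULL) {
  g <- gfp(rec)
  peaks <- find_gfp_peaks(g, min_peak_separation)
  if (length(peaks) < k)
    stop("not enough GFP peaks to fit the requested number of classes")
  rec_ar <- average_reference(rec)
  model <- cluster_topographies(rec_ar$data[, peaks, drop = FALSE], k = k,
                                n_restarts = n_restarts, seed = seed,
                                templates = templates)
  labels <- backfit(rec_ar, model)
  list(model = model, labels = labels, stats = microstate_stats(labels, rec$fs))
}
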