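#' Greedy collinearity filter for environmental variables
#'
#' Repeatedly finds the pair of variables with the largest absolute Pearson
#' correlation at or above `threshold` and drops the member of that pair
#' with the larger mean absolute correlation to all other remaining
#' variables, until no pair reaches the threshold.  Constant columns are
#' dropped first (their correlation is undefined), with a warning.
#'
#' @param env_table Data frame or matrix of numeric environmental columns.
#' @param threshold Absolute correlation cutoff in (0, 1); pairs at or
#'   above it are considered collinear.
#' @return Character vector of retained variable names, in input order.
#' @export
#' @examples
#' x <- data.frame(a = rnorm(50))
#' x$b <- x$a + rnorm(50, 0, 1e-3)   # near-duplicate
#' x$c <- rnorm(50)
#' filter_collinear(x, 0.8)
filter_collinear <- function(env_table, threshold = 0.8) {
  env_table <- as.data.frame(env_table)
  num <- vapply(env_table, is.numeric, logical(1))
  env_table <- env_table[num]
  if (ncol(env_table) < 2)
    stop("need at least two numeric columns")
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must lie strictly between 0 and 1")
  const <- vapply(env_table, function(v) sd(v, na.rm = TRUE) == 0 ||
                    is.na(sd(v, na.rm = TRUE)), logical(1))
  if (any(const)) {
    warning("dropping constant column(s): ",
            paste(names(env_table)[const], collapse = ", "))
    env_table <- env_table[!const]
  }
  keep <- names(env_table)
  cm <- abs(cor(env_table, use = "pairwise.complete.obs"))
  diag(cm) <- 0
  while (length(keep) > 1 && max(cm) >= threshold) {
    worst <- which(cm == max(cm), arr.ind = TRUE)[1, ]
    pair <- rownames(cm)[worst]
    mean_abs <- rowMeans(cm)[pair]
    drop <- pair[which.max(mean_abs)]
    keep <- setdiff(keep, drop)
    cm <- cm[keep, keep, drop = FALSE]
  }
  intersect(names(env_table), keep)
}

#' Correlation-matrix PCA of environmental variables
#'
#' Centers and scales each variable to unit variance before the
#' decomposition (a PCA "based on correlations").  The sign of each
#' eigenvector is fixed by making its largest-magnitude loading positive,
#' so output is deterministic across platforms.
#'
#' @param env_table Data frame with the environmental columns (occurrence
#'   records as rows).
#' @param variables Character vector of columns to use; default all
#'   numeric columns.
#' @return An object of class `"env_pca"`: `variables`, `center`, `scale`,
#'   `rotation` (eigenvector matrix, variables x components),
#'   `eigenvalues`, `var_prop` (proportion of variance per component) and
#'   `scores` for the fitted records.
#' @export
fit_env_pca <- function(env_table, variables = NULL) {
  env_table <- as.data.frame(env_table)
  if (is.null(variables))
    variables <- names(env_table)[vapply(env_table, is.numeric, logical(1))]
  missing_vars <- setdiff(variables, names(env_table))
  if (length(missing_vars))
    stop("variables not present: ", paste(missing_vars, collapse = ", "))
  x <- as.matrix(env_table[variables])
  if (nrow(x) < 3) stop("need at least 3 records")
  if (anyNA(x)) stop("missing values in selected variables")
  sds <- apply(x, 2, sd)
  if (any(sds == 0))
    stop("zero-variance variable(s): ",
         paste(variables[sds == 0], collapse = ", "))
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  pc$rotation <- sweep(pc$rotation, 2, flip, "*")
  pc$x <- sweep(pc$x, 2, flip, "*")
  eig <- pc$sdev^2
  structure(list(variables = variables,
                 center = pc$center,
                 scale = pc$scale,
                 rotation = pc$rotation,
                 eigenvalues = eig,
                 var_prop = eig / sum(eig),
                 scores = pc$x),
            class = "env_pca")
}

#' @export
print.env_pca <- function(x, ...) {
  cat(sprintf("Correlation-matrix PCA over %d variables, %d records\n",
              length(x$variables), nrow(x$scores)))
  vp <- round(100 * x$var_prop[seq_len(min(4, length(x$var_prop)))], 1)
  cat("  variance explained:",
      paste0("PC", seq_along(vp), " ", vp, "%", collapse = ", "), "\n")
  invisible(x)
}

#' Project new records into a fitted environmental PC space
#'
#' @param object A fitted [fit_env_pca()] object.
#' @param newdata Data frame (or named vector) containing every fitted
#'   variable.
#' @param ... Unused.
#' @return Matrix of scores (records x components).
#' @export
predict.env_pca <- function(object, newdata, ...) {
  if (is.null(dim(newdata)))
    newdata <- as.data.frame(as.list(newdata))
  missing_vars <- setdiff(object$variables, names(newdata))
  if (length(missing_vars))
    stop("missing variable(s): ", paste(missing_vars, collapse = ", "))
  x <- as.matrix(as.data.frame(newdata)[object$variables])
  x <- scale(x, center = object$center, scale = object$scale)
  x %*% object$rotation
}

#' Per-species niche median and breadth along one axis
#'
#' Breadth is the distance between the 5th and 95th percentile of the
#' species' scores; quantiles use linear interpolation between order
#' statistics (R type 7), recorded in the output.
#'
#' @param scores Numeric vector of PC scores (one axis).
#' @param labels Species label per score.
#' @return Data frame with columns `species`, `n`, `median`, `breadth`,
#'   with attribute `quantile_type = 7`.
#' @export
niche_summary <- function(scores, labels) {
  labels <- as.character(labels)
  stopifnot(length(scores) == length(labels))
  counts <- table(labels)
  if (any(counts < 2))
    stop("species with fewer than 2 records: ",
         paste(names(counts)[counts < 2], collapse = ", "))
  out <- do.call(rbind, lapply(sort(unique(labels)), function(sp) {
    s <- scores[labels == sp]
    q <- quantile(s, c(0.05, 0.95), type = 7, names = FALSE)
    data.frame(species = sp, n = length(s), median = median(s),
               breadth = q[2] - q[1], stringsAsFactors = FALSE)
  }))
  attr(out, "quantile_type") <- 7
  out
}

niche_stats <- function(scores, labels, species) {
  s1 <- scores[labels == species[1]]
  s2 <- scores[labels == species[2]]
  q1 <- quantile(s1, c(0.05, 0.95), type = 7, names = FALSE)
  q2 <- quantile(s2, c(0.05, 0.95), type = 7, names = FALSE)
  c(median = median(s1) - median(s2),
    breadth = (q1[2] - q1[1]) - (q2[2] - q2[1]))
}

#' Permutation test for species differences in niche median and breadth
#'
#' Compares the observed absolute between-species difference in median and
#' in breadth (95th minus 5th percentile) along each supplied axis with a
#' null distribution built by randomly reassigning the pooled records to
#' species.  The default null keeps group sizes fixed and reassigns
#' without replacement (a label permutation — the exchangeability null);
#' `resample = "bootstrap"` draws each pseudo-group with replacement from
#' the pool instead.  P-values use the add-one rule
#' `p = (1 + #\{null >= observed\}) / (1 + n_perm)` so they are never zero.
#'
#' @param scores Numeric vector or matrix of PC scores (columns = axes).
#' @param labels Species label per record; exactly two species.
#' @param n_perm Number of reassignments (>= 100).
#' @param seed Integer seed for the reassignment stream.
#' @param resample `"permute"` (default) or `"bootstrap"`.
#' @return An object of class `"niche_comparison"`: per axis the observed
#'   differences, null matrices (`n_perm` rows), and two-sided p-values,
#'   plus `n_perm`, `seed` and the resampling mode.
#' @export
permutation_niche_test <- function(scores, labels, n_perm = 1000, seed = 1,
                                   resample = c("permute", "bootstrap")) {
  resample <- match.arg(resample)
  scores <- as.matrix(scores)
  if (is.null(colnames(scores)))
    colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  labels <- as.character(labels)
  stopifnot(nrow(scores) == length(labels))
  species <- sort(unique(labels))
  if (length(species) != 2) stop("exactly two species are required")
  if (n_perm < 100) stop("n_perm must be at least 100")
  sizes <- table(labels)[species]
  if (any(sizes < 5))
    warning("group size below 5; the permutation null has poor resolution")

  set.seed(seed)
  n <- length(labels)
  n1 <- sizes[[1]]
  axes <- colnames(scores)
  observed <- sapply(axes, function(ax) niche_stats(scores[, ax], labels, species))
  null <- array(NA_real_, c(n_perm, 2, length(axes)),
                dimnames = list(NULL, c("median", "breadth"), axes))
  for (i in seq_len(n_perm)) {
    if (resample == "permute") {
      idx1 <- sample.int(n, n1)
      lab <- rep(species[2], n)
      lab[idx1] <- species[1]
      for (ax in axes)
        null[i, , ax] <- niche_stats(scores[, ax], lab, species)
    } else {
      for (ax in axes) {
        s1 <- sample(scores[, ax], n1, replace = TRUE)
        s2 <- sample(scores[, ax], n - n1, replace = TRUE)
        null[i, , ax] <- niche_stats(c(s1, s2),
                                     rep(species, c(n1, n - n1)), species)
      }
    }
  }
  pvals <- sapply(axes, function(ax) {
    vapply(c("median", "breadth"), function(st) {
      (1 + sum(abs(null[, st, ax]) >= abs(observed[st, ax]))) / (1 + n_perm)
    }, numeric(1))
  })
  structure(list(species = species, axes = axes,
                 observed = observed, null = null, p_values = pvals,
                 n_perm = n_perm, seed = seed, resample = resample,
                 quantile_type = 7),
            class = "niche_comparison")
}

#' @export
print.niche_comparison <- function(x, ...) {
  cat(sprintf("Niche comparison: %s vs %s (%s null, n_perm = %d)\n",
              x$species[1], x$species[2], x$resample, x$n_perm))
  for (ax in x$axes) {
    cat(sprintf("  %s: d(median) = %.3f (p = %.4g), d(breadth) = %.3f (p = %.4g)\n",
                ax, x$observed["median", ax], x$p_values["median", ax],
                x$observed["breadth", ax], x$p_values["breadth", ax]))
  }
  invisible(x)
}
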