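#' @include AllClasses.R
NULL

#' Rarefy a community count table
#'
#' Subsamples every sample (row) without replacement to a common depth, the
#' minimum row sum by default, so diversity indices are comparable across
#' samples. Row sums after rarefaction equal the depth exactly.
#'
#' @param table samples x taxa matrix of non-negative integer counts.
#' @param depth target depth; default `min(rowSums(table))`.
#' @param seed RNG seed recorded in the output attributes.
#' @return Rarefied integer matrix with attributes `depth` and `seed`.
#' @export
rarefyCounts <- function(table, depth = NULL, seed = NULL) {
  table <- as.matrix(table)
  if (any(table < 0) || any(table != round(table)))
    stop("community table must hold non-negative integers")
  rs <- rowSums(table)
  if (is.null(depth)) depth <- min(rs)
  low <- rs < depth
  if (any(low))
    stop("sample(s) below rarefaction depth ", depth, ": ",
         paste(rownames(table)[low] %||% which(low), collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  # vegan warns about "observed counts" whenever the minimum count is large;
  # inputs here are validated integer counts, so muffle that message only
  out <- withCallingHandlers(
    vegan::rrarefy(table, depth),
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  stopifnot(all(rowSums(out) == depth))
  attr(out, "depth") <- depth
  attr(out, "seed") <- seed
  out
}

#' Shannon diversity (natural log)
#'
#' `H = -sum p_i ln p_i` over nonzero taxa, per sample.
#'
#' @param counts count vector, or samples x taxa matrix.
#' @return Numeric H per sample.
#' @export
shannonIndex <- function(counts) {
  if (is.matrix(counts) || is.data.frame(counts))
    vegan::diversity(as.matrix(counts), index = "shannon")
  else vegan::diversity(matrix(counts, nrow = 1), index = "shannon")[[1]]
}

#' Taxon richness
#'
#' Number of taxa with nonzero count, per sample.
#'
#' @inheritParams shannonIndex
#' @return Integer richness per sample.
#' @export
richnessIndex <- function(counts) {
  if (is.matrix(counts) || is.data.frame(counts)) rowSums(as.matrix(counts) > 0)
  else sum(counts > 0)
}

#' Pairwise community distance matrix
#'
#' Euclidean or Bray-Curtis (`sum|x-y| / sum(x+y)`) distances between sample
#' rows. The result is checked for symmetry and a zero diagonal, and carries
#' the metric label as an attribute.
#'
#' @param mat samples x features numeric matrix.
#' @param metric "euclidean" or "bray-curtis".
#' @return Symmetric n x n matrix with attribute `metric`.
#' @export
communityDistance <- function(mat, metric = c("euclidean", "bray-curtis")) {
  metric <- match.arg(metric)
  d <- as.matrix(vegan::vegdist(as.matrix(mat),
                                method = if (metric == "euclidean") "euclidean" else "bray"))
  stopifnot(isTRUE(all.equal(d, t(d))), all(diag(d) == 0))
  if (metric == "bray-curtis") stopifnot(all(d >= 0 & d <= 1 + 1e-12))
  attr(d, "metric") <- metric
  d
}

.lowerTri <- function(m) m[lower.tri(m)]

.checkDistanceMatrix <- function(d, name) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || !isTRUE(all.equal(d, t(d), check.attributes = FALSE)))
    stop(name, " is not a symmetric square matrix")
  if (any(abs(diag(d)) > 1e-12)) stop(name, " has a nonzero diagonal")
  d
}

#' Mantel test between two distance matrices
#'
#' The statistic is the Pearson correlation of the lower triangles; the
#' one-sided upper p-value is estimated by jointly permuting the row/column
#' order of the second matrix, with add-one smoothing:
#' `p = (1 + #[r_perm >= r_obs]) / (permutations + 1)`. With
#' `exact = TRUE` all n! permutations are enumerated and the p-value is the
#' exact fraction with `r_perm >= r_obs`.
#'
#' @param dx,dy distance matrices of equal dimension.
#' @param permutations number of random permutations (default 999).
#' @param seed RNG seed.
#' @param exact enumerate all permutations (feasible for small n).
#' @return List with `r`, `p`, `permutations`.
#' @export
mantelTest <- function(dx, dy, permutations = 999, seed = NULL, exact = FALSE) {
  dx <- .checkDistanceMatrix(dx, "dx")
  dy <- .checkDistanceMatrix(dy, "dy")
  if (!all(dim(dx) == dim(dy))) stop("dx and dy must have the same dimension")
  n <- nrow(dx)
  x <- .lowerTri(dx)
  robs <- stats::cor(x, .lowerTri(dy))
  if (exact) {
    perms <- .allPermutations(n)
    rs <- vapply(perms, function(p) stats::cor(x, .lowerTri(dy[p, p])), numeric(1))
    return(list(r = robs, p = mean(rs >= robs - 1e-12), permutations = length(perms)))
  }
  if (!is.null(seed)) set.seed(seed)
  exceed <- 0L
  for (i in seq_len(permutations)) {
    p <- sample.int(n)
    if (stats::cor(x, .lowerTri(dy[p, p])) >= robs - 1e-12) exceed <- exceed + 1L
  }
  list(r = robs, p = (1 + exceed) / (permutations + 1), permutations = permutations)
}

.allPermutations <- function(n) {
  if (n > 8) stop("exact enumeration limited to n <= 8")
  if (n == 1) return(list(1L))
  sub <- .allPermutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (s in sub) for (pos in seq_len(n)) {
    k <- k + 1L
    out[[k]] <- append(s, n, after = pos - 1L)
  }
  out
}

#' Ordinary least-squares regression of a diversity index on abundance
#'
#' @param x predictor (e.g. log2 producer abundance).
#' @param y response (e.g. Shannon index).
#' @return List with `slope`, `intercept`, `r2`, `p` (t-test on the slope).
#' @export
linRegress <- function(x, y) {
  fit <- stats::lm(y ~ x)
  s <- suppressWarnings(summary(fit))  # tolerate exact fits
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r2 = s$r.squared,
       p = unname(s$coefficients[2, 4]))
}

#' Spearman correlation screen with BH false-discovery control
#'
#' Correlates one abundance vector against every feature column (average
#' ranks for ties) and adjusts p-values with Benjamini-Hochberg.
#'
#' @param abundance numeric vector (length = samples).
#' @param features samples x features numeric matrix.
#' @return data.frame: `feature`, `rho`, `p`, `q`.
#' @export
spearmanFdr <- function(abundance, features) {
  features <- as.matrix(features)
  stopifnot(length(abundance) == nrow(features))
  res <- apply(features, 2, function(f) {
    ct <- suppressWarnings(stats::cor.test(abundance, f, method = "spearman"))
    c(rho = unname(ct$estimate), p = ct$p.value)
  })
  out <- data.frame(feature = colnames(features) %||% as.character(seq_len(ncol(features))),
                    rho = res["rho", ], p = res["p", ],
                    stringsAsFactors = FALSE)
  out$q <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact by enumeration of all `choose(nA+nB, nA)` group assignments when
#' `nA + nB <= 12` (ties handled through average ranks, with
#' `p = 2 min(P(W <= w), P(W >= w))` capped at 1); otherwise the normal
#' approximation with the tie-corrected variance.
#'
#' @param a,b numeric samples for the two groups.
#' @return Two-sided p-value.
#' @export
wilcoxonRankSum <- function(a, b) {
  na <- length(a); nb <- length(b); n <- na + nb
  if (na == 0 || nb == 0) stop("both groups must be non-empty")
  r <- rank(c(a, b))
  w <- sum(r[seq_len(na)])
  if (n <= 12) {
    combos <- utils::combn(n, na)
    ws <- colSums(matrix(r[combos], nrow = na))
    p <- 2 * min(mean(ws <= w + 1e-9), mean(ws >= w - 1e-9))
    return(min(1, p))
  }
  mu <- na * (n + 1) / 2
  ties <- table(r)
  sig2 <- na * nb / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sig2 == 0) return(1)
  z <- (w - mu) / sqrt(sig2)
  2 * stats::pnorm(-abs(z))
}

#' Volcano table of pathway discovery rates: producers vs nonproducers
#'
#' For each metabolic pathway, compares its discovery rate (fraction of MAGs
#' carrying it) between producer and nonproducer MAGs. Rates use the Haldane
#' correction `(k + 0.5) / (n + 1)` so fold changes are defined at zero
#' counts; p-values come from the rank-sum test on the presence indicators
#' and are BH-adjusted. Callers following the standard workflow should exclude
#' nonproducer MAGs that are also nonusers before calling.
#'
#' @param presence MAGs x pathways logical (or 0/1) matrix.
#' @param producerFlags logical vector per MAG.
#' @param alpha significance level on the adjusted p-value (default 0.05).
#' @return data.frame: `pathway_id`, `rate_producer`, `rate_nonproducer`,
#'   `log2fc`, `p_value`, `q_value`, `significant`, `direction`.
#' @export
volcanoTable <- function(presence, producerFlags, alpha = 0.05) {
  presence <- as.matrix(presence) * 1
  stopifnot(nrow(presence) == length(producerFlags))
  pr <- presence[producerFlags, , drop = FALSE]
  np <- presence[!producerFlags, , drop = FALSE]
  if (!nrow(pr) || !nrow(np)) stop("need both producer and nonproducer MAGs")
  ratep <- (colSums(pr) + 0.5) / (nrow(pr) + 1)
  ratenp <- (colSums(np) + 0.5) / (nrow(np) + 1)
  lfc <- log2(ratep / ratenp)
  pv <- vapply(seq_len(ncol(presence)),
               function(j) wilcoxonRankSum(pr[, j], np[, j]), numeric(1))
  qv <- stats::p.adjust(pv, method = "BH")
  data.frame(pathway_id = colnames(presence) %||% as.character(seq_len(ncol(presence))),
             rate_producer = ratep, rate_nonproducer = ratenp,
             log2fc = lfc, p_value = pv, q_value = qv,
             significant = qv < alpha & abs(lfc) > 0,
             direction = ifelse(lfc > 0, "up", ifelse(lfc < 0, "down", "none")),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Aggregate gene abundances into nutrient-cycle processes
#'
#' Process value = sum of member gene abundances; whole-cycle value = sum of
#' the process values.
#'
#' @param geneAbundances named numeric vector, or samples x genes matrix.
#' @param geneToProcess named character vector mapping gene to process.
#' @return List with `process` (vector or samples x processes matrix) and
#'   `cycle` (scalar or per-sample total).
#' @export
cycleAggregate <- function(geneAbundances, geneToProcess) {
  procs <- sort(unique(unname(geneToProcess)))
  if (is.matrix(geneAbundances)) {
    genes <- colnames(geneAbundances)
    proc <- sapply(procs, function(p) {
      members <- intersect(genes, names(geneToProcess)[geneToProcess == p])
      if (!length(members)) return(rep(0, nrow(geneAbundances)))
      rowSums(geneAbundances[, members, drop = FALSE])
    })
    proc <- matrix(proc, nrow = nrow(geneAbundances),
                   dimnames = list(rownames(geneAbundances), procs))
    list(process = proc, cycle = rowSums(proc))
  } else {
    proc <- vapply(procs, function(p) {
      members <- intersect(names(geneAbundances),
                           names(geneToProcess)[geneToProcess == p])
      sum(geneAbundances[members])
    }, numeric(1))
    list(process = proc, cycle = sum(proc))
  }
}
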