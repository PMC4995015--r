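#' Bruvo distance between two alleles
#'
#' Distance under the stepwise mutation model: with
#' \eqn{x = |a - b| / \mathrm{unit}} rounded to the nearest integer (ties
#' away from zero), the distance is \eqn{1 - 2^{-x}}, in \eqn{[0, 1)}.
#' Identical alleles give 0; each extra repeat unit halves the remaining
#' distance to 1.
#'
#' @param a,b allele sizes in bp (vectorised).
#' @param unit_length repeat-unit length in bp (>= 1).
#' @return Fractional distance(s) in \eqn{[0, 1)}.
#' @export
bruvo_allele_distance <- function(a, b, unit_length) {
  stopifnot(all(unit_length >= 1))
  x <- floor(abs(a - b) / unit_length + 0.5)  # ties away from zero (x >= 0)
  1 - 2^(-x)
}

#' Bruvo distance between two diploid genotypes at one locus
#'
#' The minimum over the two perfect matchings of the allele pairs of the
#' mean per-pair allele distance (both genotypes diploid, equal ploidy).
#'
#' @param g1,g2 length-2 vectors of allele sizes at the same locus.
#' @param unit_length repeat-unit length in bp.
#' @return Fractional distance in \eqn{[0, 1)}.
#' @export
bruvo_locus_distance <- function(g1, g2, unit_length) {
  stopifnot(length(g1) == 2L, length(g2) == 2L)
  m1 <- (bruvo_allele_distance(g1[1], g2[1], unit_length) +
         bruvo_allele_distance(g1[2], g2[2], unit_length)) / 2
  m2 <- (bruvo_allele_distance(g1[1], g2[2], unit_length) +
         bruvo_allele_distance(g1[2], g2[1], unit_length)) / 2
  min(m1, m2)
}

#' Bruvo distance between two multilocus genotypes
#'
#' Unweighted mean of the per-locus diploid distances over the full panel.
#'
#' @param m1,m2 \code{mlg_set} objects holding a single genotype each, or a
#'   shared \code{mlg_set} with \code{i}, \code{j} row indices.
#' @param i,j optional row indices when \code{m1} holds both genotypes.
#' @return Fractional distance in \eqn{[0, 1)}.
#' @export
bruvo_mlg_distance <- function(m1, m2 = NULL, i = 1L, j = 2L) {
  if (is.null(m2)) { m2 <- m1 } else {
    if (!identical(m1$loci$name, m2$loci$name) ||
        !identical(m1$loci$unit_length, m2$loci$unit_length))
      stop("locus panels differ")
    j <- if (missing(j)) 1L else j
  }
  u <- m1$loci$unit_length
  d <- vapply(seq_len(nrow(m1$loci)), function(l) {
    bruvo_locus_distance(m1$alleles[i, l, ], m2$alleles[j, l, ], u[l])
  }, 0)
  mean(d)
}

#' Full Bruvo distance matrix
#'
#' Pairwise Bruvo distances between all genotypes of \code{mlgs}, or the
#' rectangular cross-distance against \code{other}. Computed vectorised per
#' locus; the full symmetric matrix is cached by callers rather than
#' recomputed, so downstream permutation tests see one consistent matrix.
#'
#' @param mlgs an \code{mlg_set}.
#' @param other optional second \code{mlg_set} (e.g. the commercial panel).
#' @return Numeric matrix of distances in \eqn{[0, 1)}, with MLG ids as
#'   dimnames; symmetric with zero diagonal in the single-set case.
#' @export
bruvo_dist <- function(mlgs, other = NULL) {
  sym <- is.null(other)
  if (sym) other <- mlgs
  if (!identical(mlgs$loci$name, other$loci$name)) stop("locus panels differ")
  u <- mlgs$loci$unit_length
  n1 <- n_mlg(mlgs); n2 <- n_mlg(other)
  acc <- matrix(0, n1, n2)
  for (l in seq_len(nrow(mlgs$loci))) {
    p <- mlgs$alleles[, l, , drop = FALSE]
    q <- other$alleles[, l, , drop = FALSE]
    d11 <- bruvo_allele_distance(outer(p[, 1, 1], q[, 1, 1], "-"), 0, u[l])
    d22 <- bruvo_allele_distance(outer(p[, 1, 2], q[, 1, 2], "-"), 0, u[l])
    d12 <- bruvo_allele_distance(outer(p[, 1, 1], q[, 1, 2], "-"), 0, u[l])
    d21 <- bruvo_allele_distance(outer(p[, 1, 2], q[, 1, 1], "-"), 0, u[l])
    acc <- acc + pmin((d11 + d22) / 2, (d12 + d21) / 2)
  }
  out <- acc / nrow(mlgs$loci)
  dimnames(out) <- list(mlgs$ids, other$ids)
  if (sym) { out[lower.tri(out)] <- t(out)[lower.tri(out)]; diag(out) <- 0 }
  out
}

#' Classification thresholds for commercial relatedness
#'
#' @param related_threshold minimum Bruvo distance below which an MLG is
#'   called commercial-related (default 0.25, the valley of the bimodal
#'   distance distribution); the boundary itself classifies as unique.
#' @param far_threshold distance beyond which genotypes are reported as
#'   distinct from the commercial pool (default 0.43; reporting only).
#' @param histogram_bin bin width for the min-distance histogram (0.05).
#' @return A list of class \code{classification_config}.
#' @export
classification_config <- function(related_threshold = 0.25,
                                  far_threshold = 0.43,
                                  histogram_bin = 0.05) {
  stopifnot(related_threshold > 0, related_threshold < far_threshold,
            far_threshold < 1, histogram_bin > 0)
  structure(list(related_threshold = related_threshold,
                 far_threshold = far_threshold,
                 histogram_bin = histogram_bin),
            class = "classification_config")
}

#' Classify MLGs as commercial, commercial-related or unique
#'
#' An MLG identical to a panel strain (exact match at all 16 alleles) is
#' \emph{commercial}; otherwise its minimum Bruvo distance to the panel
#' decides: strictly below the related threshold it is
#' \emph{commercial_related} (labelled \code{SB_<nearest strain>}), at or
#' above it \emph{unique}. Also returns the frequency histogram of minimum
#' distances (0.05-unit bins), whose bimodality motivates the threshold.
#'
#' @param mlgs an \code{mlg_set} of query genotypes.
#' @param panel an \code{mlg_set} of commercial strains (non-empty).
#' @param cfg a \code{classification_config}.
#' @param matches optional precomputed \code{\link{match_commercial}} result.
#' @param dist_to_panel optional precomputed cross-distance matrix.
#' @return A list with \code{classification} (data frame: mlg_id, category,
#'   nearest_commercial, min_distance, derived_label) and \code{histogram}
#'   (data frame: bin_lo, bin_hi, count).
#' @export
classify_mlgs <- function(mlgs, panel, cfg = classification_config(),
                          matches = NULL, dist_to_panel = NULL) {
  if (n_mlg(panel) == 0L) stop("reference panel is empty")
  if (is.null(matches)) matches <- match_commercial(mlgs, panel, tolerance_bp = 0L)
  if (is.null(dist_to_panel)) dist_to_panel <- bruvo_dist(mlgs, panel)
  nearest_i <- apply(dist_to_panel, 1, which.min)
  min_d <- dist_to_panel[cbind(seq_len(n_mlg(mlgs)), nearest_i)]
  nearest <- panel$ids[nearest_i]
  exact <- matches$match_mode == "exact"
  min_d[exact] <- 0
  nearest[exact] <- matches$matched_strain[exact]
  category <- ifelse(exact, "commercial",
                     ifelse(min_d < cfg$related_threshold,
                            "commercial_related", "unique"))
  label <- ifelse(category == "commercial_related", paste0("SB_", nearest),
                  ifelse(category == "commercial", nearest, mlgs$ids))
  cls <- data.frame(mlg_id = mlgs$ids, category = category,
                    nearest_commercial = nearest, min_distance = min_d,
                    derived_label = label, stringsAsFactors = FALSE)
  breaks <- seq(0, ceiling(1 / cfg$histogram_bin) * cfg$histogram_bin,
                by = cfg$histogram_bin)
  # distances are < 1 in exact arithmetic but can round to 1.0 in doubles
  cnt <- table(cut(pmin(min_d, max(breaks) - 1e-12),
                   breaks = breaks, right = FALSE))
  hist <- data.frame(bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1],
                     count = as.integer(cnt))
  list(classification = cls, histogram = hist)
}

#' Export a distance matrix in square PHYLIP format
#'
#' @param dm symmetric numeric matrix with row names.
#' @param path output path.
#' @export
write_phylip_dm <- function(dm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  cat(sprintf("%5d\n", nrow(dm)), file = con)
  labs <- sprintf("%-10s", substr(rownames(dm), 1, 10))
  for (i in seq_len(nrow(dm)))
    cat(labs[i], sprintf("%.6f", dm[i, ]), "\n", file = con)
  invisible(path)
}
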