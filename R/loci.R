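#' Microsatellite locus definitions
#'
#' A locus table describes the SSR panel used for typing: one row per locus
#' with its repeat motif, repeat-unit length in bp (the step size of the
#' stepwise mutation model) and chromosome.
#'
#' @param name character vector of locus identifiers.
#' @param motif repeat-unit sequence (e.g. \code{"CAA"}).
#' @param unit_length integer repeat-unit length in bp; must be >= 1.
#' @param chromosome optional chromosome label.
#' @return A data frame of class \code{locus_table}.
#' @export
locus_table <- function(name, motif, unit_length, chromosome = NA_character_) {
  stopifnot(length(name) == length(motif), length(motif) == length(unit_length))
  unit_length <- as.integer(unit_length)
  if (any(is.na(unit_length)) || any(unit_length < 1L))
    stop("unit_length must be an integer >= 1 for every locus")
  if (anyDuplicated(name))
    stop("locus names must be unique")
  out <- data.frame(name = as.character(name), motif = as.character(motif),
                    unit_length = unit_length,
                    chromosome = rep_len(as.character(chromosome), length(name)),
                    stringsAsFactors = FALSE)
  class(out) <- c("locus_table", "data.frame")
  out
}

#' Default 8-locus S. cerevisiae SSR panel
#'
#' The eight polymorphic loci used for wine-yeast strain typing, with their
#' repeat motifs and unit lengths (CAA = 3 bp, GT = 2 bp, TAA = 3 bp,
#' TAA+TAG = 3 bp, AAT = 3 bp, TA = 2 bp, AAT = 3 bp, CTT = 3 bp).
#'
#' @return A \code{locus_table} with 8 rows.
#' @export
default_loci <- function() {
  locus_table(
    name        = c("YGL139W", "YFR028C", "YGL014W", "YOL109W",
                    "YML091C", "YLL049W", "YDR160W", "YPL009C"),
    motif       = c("CAA", "GT", "TAA", "TAA+TAG", "AAT", "TA", "AAT", "CTT"),
    unit_length = c(3L, 2L, 3L, 3L, 3L, 2L, 3L, 3L),
    chromosome  = c("VII", "VI", "VII", "XV", "XIII", "XII", "IV", "XVI")
  )
}

#' Construct a set of multilocus genotypes
#'
#' An \code{mlg_set} is the package's core container: a set of diploid
#' multilocus genotypes (MLGs) over a fixed locus panel. Allele sizes are
#' stored as an integer array of dimension \code{n x L x 2}, each allele
#' pair sorted ascending (phase is never represented; a homozygote is a
#' duplicated value).
#'
#' @param alleles integer array \code{n x L x 2} of allele sizes in bp, or an
#'   \code{n x 2L} matrix with paired columns (locus1.1, locus1.2, ...).
#' @param ids character vector of MLG identifiers (unique).
#' @param loci a \code{locus_table}.
#' @return An object of class \code{mlg_set}.
#' @export
mlg_set <- function(alleles, ids, loci = default_loci()) {
  L <- nrow(loci)
  if (is.matrix(alleles)) {
    if (ncol(alleles) != 2L * L)
      stop("allele matrix must have 2 columns per locus")
    alleles <- array(as.integer(alleles[, c(seq(1L, 2L * L, 2L), seq(2L, 2L * L, 2L)),
                                         drop = FALSE]),
                     dim = c(nrow(alleles), L, 2L))
  }
  stopifnot(length(dim(alleles)) == 3L, dim(alleles)[2] == L, dim(alleles)[3] == 2L)
  if (length(ids) != dim(alleles)[1]) stop("one id per genotype required")
  if (anyDuplicated(ids)) stop("MLG ids must be unique")
  if (anyNA(alleles)) stop("mlg_set does not hold incomplete profiles")
  storage.mode(alleles) <- "integer"
  # sort each allele pair ascending
  swap <- alleles[, , 1, drop = FALSE] > alleles[, , 2, drop = FALSE]
  if (any(swap)) {
    lo <- pmin(alleles[, , 1], alleles[, , 2])
    hi <- pmax(alleles[, , 1], alleles[, , 2])
    alleles <- array(c(lo, hi), dim = dim(alleles))
  }
  dimnames(alleles) <- list(as.character(ids), loci$name, c("a1", "a2"))
  structure(list(ids = as.character(ids), alleles = alleles, loci = loci),
            class = "mlg_set")
}

#' @export
print.mlg_set <- function(x, ...) {
  cat(sprintf("mlg_set: %d diploid multilocus genotypes over %d loci (%s)\n",
              n_mlg(x), nrow(x$loci), paste(x$loci$name, collapse = ", ")))
  invisible(x)
}

#' Number of genotypes in an mlg_set
#' @param x an \code{mlg_set}.
#' @return integer count.
#' @export
n_mlg <- function(x) length(x$ids)

#' Subset an mlg_set
#' @param x an \code{mlg_set}.
#' @param i index vector (logical, integer or id character).
#' @param ... unused.
#' @export
`[.mlg_set` <- function(x, i, ...) {
  if (is.character(i)) i <- match(i, x$ids)
  mlg_set(x$alleles[i, , , drop = FALSE], x$ids[i], x$loci)
}

#' Combine mlg_sets over the same locus panel
#' @param ... \code{mlg_set} objects with identical loci.
#' @return a single \code{mlg_set}.
#' @export
c_mlg <- function(...) {
  sets <- list(...)
  loci <- sets[[1]]$loci
  for (s in sets) {
    if (!identical(s$loci$name, loci$name)) stop("locus panels differ")
  }
  alleles <- do.call(abind3, lapply(sets, `[[`, "alleles"))
  mlg_set(alleles, unlist(lapply(sets, `[[`, "ids")), loci)
}

# rbind for n x L x 2 arrays
abind3 <- function(...) {
  xs <- list(...)
  d <- dim(xs[[1]])
  n <- sum(vapply(xs, function(a) dim(a)[1], 1L))
  out <- array(NA_integer_, dim = c(n, d[2], d[3]))
  at <- 0L
  for (a in xs) {
    out[at + seq_len(dim(a)[1]), , ] <- a
    at <- at + dim(a)[1]
  }
  out
}

# profile key used for MLG identity: all allele pairs at all loci
profile_key <- function(alleles) {
  n <- dim(alleles)[1]
  flat <- matrix(alleles, nrow = n)
  apply(flat, 1, paste, collapse = "/")
}
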