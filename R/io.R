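#' Read an isolate genotype table
#'
#' Reads a delimited text file (CSV or TSV, autodetected by extension) with
#' one row per isolate: metadata columns \code{isolate_id, location, vintage,
#' fermentation_id, stage} followed by two allele-size columns per locus,
#' named \code{<locus>.1} and \code{<locus>.2}. Rows with any missing or
#' unparseable allele are excluded (the typing protocol drops isolates whose
#' profile stays incomplete after re-amplification), and the exclusions are
#' reported with a reason. Identical 8-locus profiles are collapsed into one
#' multilocus genotype (MLG): the operational definition of a strain.
#'
#' @param path path to the delimited file.
#' @param loci a \code{locus_table}; defaults to the 8-locus panel.
#' @param stages valid stage levels, in temporal order.
#' @return A list with \code{isolates} (data frame with an \code{mlg_id}
#'   column), \code{mlgs} (an \code{mlg_set} of the distinct genotypes) and
#'   \code{excluded} (data frame of dropped rows with reasons).
#' @export
read_isolate_table <- function(path, loci = default_loci(),
                               stages = c("early", "mid", "late")) {
  raw <- read_delimited(path)
  meta_cols <- c("isolate_id", "location", "vintage", "fermentation_id", "stage")
  missing_meta <- setdiff(meta_cols, names(raw))
  if (length(missing_meta))
    stop("missing required metadata column(s): ", paste(missing_meta, collapse = ", "))
  parsed <- parse_genotype_columns(raw, loci)
  keep <- parsed$complete
  excluded <- data.frame(row = which(!keep),
                         isolate_id = as.character(raw$isolate_id[!keep]),
                         reason = parsed$reason[!keep],
                         stringsAsFactors = FALSE)
  if (!any(keep)) stop("no rows with complete genotype profiles in ", path)
  iso <- raw[keep, meta_cols]
  bad_stage <- !(iso$stage %in% stages)
  if (any(bad_stage))
    stop("unknown stage value(s): ", paste(unique(iso$stage[bad_stage]), collapse = ", "))
  alle <- parsed$alleles[keep, , , drop = FALSE]
  key <- profile_key(alle)
  first <- !duplicated(key)
  mlg_ids <- sprintf("MLG%03d", seq_len(sum(first)))
  iso$mlg_id <- mlg_ids[match(key, key[first])]
  rownames(iso) <- NULL
  mlgs <- mlg_set(alle[first, , , drop = FALSE], mlg_ids, loci)
  list(isolates = iso, mlgs = mlgs, excluded = excluded)
}

#' Read a commercial-strain reference panel
#'
#' Same layout as the isolate table but with a single metadata column
#' \code{strain_name}. All entries must be complete over the locus panel and
#' strain names unique.
#'
#' @inheritParams read_isolate_table
#' @return An \code{mlg_set} whose ids are the commercial strain names.
#' @export
read_reference_panel <- function(path, loci = default_loci()) {
  raw <- read_delimited(path)
  if (!"strain_name" %in% names(raw))
    stop("missing required metadata column(s): strain_name")
  parsed <- parse_genotype_columns(raw, loci)
  if (!all(parsed$complete))
    stop("reference panel entries must be complete: ",
         paste(raw$strain_name[!parsed$complete], collapse = ", "))
  mlg_set(parsed$alleles, raw$strain_name, loci)
}

read_delimited <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE, colClasses = "character",
                    blank.lines.skip = TRUE)
}

parse_genotype_columns <- function(raw, loci) {
  cols <- as.vector(rbind(paste0(loci$name, ".1"), paste0(loci$name, ".2")))
  missing_cols <- setdiff(cols, names(raw))
  if (length(missing_cols))
    stop("missing allele column(s): ", paste(missing_cols, collapse = ", "))
  n <- nrow(raw)
  L <- nrow(loci)
  alle <- array(NA_integer_, dim = c(n, L, 2L))
  for (l in seq_len(L)) {
    for (a in 1:2) {
      v <- suppressWarnings(as.numeric(raw[[paste0(loci$name[l], ".", a)]]))
      alle[, l, a] <- as.integer(round(v))
    }
  }
  complete <- !apply(is.na(alle), 1, any)
  reason <- ifelse(complete, NA_character_, "missing or unparseable allele")
  list(alleles = alle, complete = complete, reason = reason)
}

#' Bin raw fragment sizes into integer alleles
#'
#' Greedy single-linkage binning in ascending size order: a size within
#' \code{tolerance} of the running centre (mean of current members) of the
#' open bin joins it; otherwise a new bin starts. Each bin's allele value is
#' the rounded mean of its members. Deterministic for a fixed multiset of
#' input sizes.
#'
#' @param raw_sizes numeric vector of fractional fragment sizes in bp.
#' @param tolerance maximum distance in bp from the bin centre; must be > 0.
#' @return Integer vector of binned allele sizes, parallel to the input. A
#'   warning is raised if two final bin values end up closer than
#'   \code{tolerance} (bins are kept distinct).
#' @export
bin_alleles <- function(raw_sizes, tolerance = 0.5) {
  stopifnot(tolerance > 0, length(raw_sizes) >= 1, !anyNA(raw_sizes))
  ord <- order(raw_sizes)
  s <- raw_sizes[ord]
  bin_id <- integer(length(s))
  centre <- s[1]
  members <- 1L
  id <- 1L
  bin_id[1] <- 1L
  for (i in seq_along(s)[-1]) {
    if (s[i] - centre <= tolerance) {
      members <- members + 1L
      centre <- centre + (s[i] - centre) / members
    } else {
      id <- id + 1L
      centre <- s[i]
      members <- 1L
    }
    bin_id[i] <- id
  }
  values <- as.integer(round(tapply(s, bin_id, mean)))
  if (id > 1L && any(diff(values) < tolerance))
    warning("bin centres closer than the tolerance; bins kept distinct")
  out <- integer(length(s))
  out[ord] <- values[bin_id]
  out
}

#' Clone-censor an isolate table
#'
#' Retains each multilocus genotype exactly once per group (by default per
#' sampling location), removing clonal oversampling before population-genetic
#' inference. The same MLG may remain in several groups. Idempotent.
#'
#' @param isolates data frame with an \code{mlg_id} column.
#' @param by name of the grouping metadata column (default \code{"location"}).
#' @return The censored data frame (first record of each MLG per group).
#' @export
clone_censor <- function(isolates, by = "location") {
  if (!by %in% names(isolates)) stop("grouping column not found: ", by)
  if (!"mlg_id" %in% names(isolates)) stop("isolates must carry mlg_id")
  keep <- !duplicated(paste(isolates[[by]], isolates$mlg_id, sep = "\r"))
  out <- isolates[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Match multilocus genotypes against the commercial panel
#'
#' For each query MLG, looks for a commercial reference strain with the same
#' profile. An exact match (all 16 alleles identical) is preferred; otherwise
#' a tolerant match requires every allele within \code{tolerance_bp} of the
#' candidate's corresponding allele (pairs compared after ascending sort).
#' Among several tolerant candidates the one with the smallest total absolute
#' deviation wins; ties go to the lexicographically first strain name.
#'
#' @param mlgs an \code{mlg_set} of query genotypes.
#' @param panel an \code{mlg_set} of named commercial strains.
#' @param tolerance_bp integer bp tolerance per allele (default 1, the
#'   screening rule used for cross-database comparisons); 0 means exact only.
#' @return Data frame with one row per query: \code{mlg_id},
#'   \code{matched_strain} (NA if none), \code{match_mode} in
#'   \{exact, tolerant, none\} and \code{max_allele_deviation} in bp.
#' @export
match_commercial <- function(mlgs, panel, tolerance_bp = 1L) {
  stopifnot(tolerance_bp >= 0)
  if (!identical(mlgs$loci$name, panel$loci$name)) stop("locus panels differ")
  if (n_mlg(panel) == 0L) stop("reference panel is empty")
  nq <- n_mlg(mlgs)
  L <- nrow(mlgs$loci)
  qa <- matrix(mlgs$alleles, nrow = nq)       # n x 2L
  pa <- matrix(panel$alleles, nrow = n_mlg(panel))
  res <- data.frame(mlg_id = mlgs$ids, matched_strain = NA_character_,
                    match_mode = "none", max_allele_deviation = NA_integer_,
                    stringsAsFactors = FALSE)
  ord <- order(panel$ids)
  for (i in seq_len(nq)) {
    dev <- abs(sweep(pa, 2, qa[i, ]))        # panel x 2L
    maxdev <- apply(dev, 1, max)
    exact <- which(maxdev == 0L)
    if (length(exact)) {
      j <- exact[order(panel$ids[exact])][1]
      res$matched_strain[i] <- panel$ids[j]
      res$match_mode[i] <- "exact"
      res$max_allele_deviation[i] <- 0L
    } else if (tolerance_bp > 0) {
      ok <- which(maxdev <= tolerance_bp)
      if (length(ok)) {
        tot <- rowSums(dev[ok, , drop = FALSE])
        best <- ok[tot == min(tot)]
        j <- best[order(panel$ids[best])][1]
        res$matched_strain[i] <- panel$ids[j]
        res$match_mode[i] <- "tolerant"
        res$max_allele_deviation[i] <- as.integer(maxdev[j])
      }
    }
  }
  res
}

#' Export genotypes in STRUCTURE one-row-per-allele-copy format
#'
#' Writes two whitespace-delimited rows per genotype (one per allele copy):
#' id, optional group label, then one allele size per locus.
#'
#' @param mlgs an \code{mlg_set}.
#' @param path output file path.
#' @param groups optional group label per genotype.
#' @export
write_structure <- function(mlgs, path, groups = NULL) {
  n <- n_mlg(mlgs)
  if (is.null(groups)) groups <- rep(1L, n)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(n)) {
    for (a in 1:2) {
      cat(mlgs$ids[i], as.character(groups[i]), mlgs$alleles[i, , a],
          file = con, sep = " ")
      cat("\n", file = con)
    }
  }
  invisible(path)
}

#' Write an isolate table (with genotypes) to delimited text
#'
#' Inverse of \code{\link{read_isolate_table}}: emits metadata columns plus
#' two allele columns per locus, resolving each isolate's \code{mlg_id}
#' against \code{mlgs}.
#'
#' @param isolates isolate data frame with \code{mlg_id}.
#' @param mlgs \code{mlg_set} holding the referenced genotypes.
#' @param path output path (.csv or .tsv).
#' @export
write_isolate_table <- function(isolates, mlgs, path) {
  idx <- match(isolates$mlg_id, mlgs$ids)
  if (anyNA(idx)) stop("isolates reference unknown mlg_id")
  L <- nrow(mlgs$loci)
  flat <- matrix(mlgs$alleles, nrow = n_mlg(mlgs))[idx, , drop = FALSE]
  geno <- flat[, as.vector(rbind(seq_len(L), L + seq_len(L))), drop = FALSE]
  colnames(geno) <- as.vector(rbind(paste0(mlgs$loci$name, ".1"),
                                    paste0(mlgs$loci$name, ".2")))
  out <- cbind(isolates[c("isolate_id", "location", "vintage",
                          "fermentation_id", "stage")], as.data.frame(geno))
  sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
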