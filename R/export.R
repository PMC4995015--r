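#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor-joining (via \code{ape::nj}) on a Bruvo distance
#' matrix, as a portable stand-in for a split network: together with the
#' PHYLIP export of the raw matrix any external network tool can redo the
#' figure. Negative branch lengths are clamped to 0 with the deficit moved
#' to the sibling edge, preserving path lengths through the parent node.
#'
#' @param dm symmetric distance matrix with >= 3 labels.
#' @return An \code{ape::phylo} tree with non-negative branch lengths.
#' @export
nj_tree <- function(dm) {
  dm <- as.matrix(dm)
  if (nrow(dm) < 3L) stop("at least 3 labels required")
  tr <- ape::nj(stats::as.dist(dm))
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    parent <- tr$edge[e, 1]
    sibs <- which(tr$edge[, 1] == parent & seq_len(nrow(tr$edge)) != e)
    if (length(sibs)) {
      tr$edge.length[sibs[1]] <- tr$edge.length[sibs[1]] + tr$edge.length[e]
    }
    tr$edge.length[e] <- 0
  }
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' MLG-type frequencies per fermentation stage
#'
#' Per fermentation and stage, the proportions of isolates whose MLG is
#' classified commercial, commercial-related or unique. Sample points with
#' fewer than \code{min_isolates} isolates are flagged and excluded from the
#' frequency table (kept in the output with \code{excluded = TRUE}).
#'
#' @param isolates isolate data frame with \code{mlg_id}, \code{location},
#'   \code{vintage}, \code{fermentation_id}, \code{stage}.
#' @param classification data frame from \code{\link{classify_mlgs}}.
#' @param min_isolates minimum isolates per sample point (default 10).
#' @param stages stage order (early < mid < late).
#' @return Data frame: location, vintage, fermentation_id, stage, n,
#'   freq_commercial, freq_commercial_related, freq_unique, excluded.
#' @export
stage_frequencies <- function(isolates, classification, min_isolates = 10,
                              stages = c("early", "mid", "late")) {
  cat_of <- classification$category[match(isolates$mlg_id, classification$mlg_id)]
  if (anyNA(cat_of)) stop("classification missing for some isolate MLGs")
  key <- interaction(isolates$location, isolates$vintage,
                     isolates$fermentation_id, isolates$stage, drop = TRUE)
  rows <- lapply(levels(key), function(kk) {
    sel <- key == kk
    first <- which(sel)[1]
    n <- sum(sel)
    f <- function(cc) sum(cat_of[sel] == cc) / n
    data.frame(location = isolates$location[first],
               vintage = isolates$vintage[first],
               fermentation_id = isolates$fermentation_id[first],
               stage = isolates$stage[first], n = n,
               freq_commercial = f("commercial"),
               freq_commercial_related = f("commercial_related"),
               freq_unique = f("unique"),
               excluded = n < min_isolates)
  })
  out <- do.call(rbind, rows)
  out$stage <- factor(out$stage, levels = stages, ordered = TRUE)
  out <- out[order(out$location, out$vintage, out$fermentation_id, out$stage), ]
  rownames(out) <- NULL
  out
}

#' MLG overlap between groups (Venn region counts)
#'
#' Partitions the distinct MLGs by the exact combination of groups they were
#' isolated from (exclusive Venn regions: an MLG counts once, in the region
#' of its full group set) and reports counts per region, split by
#' classification category when one is supplied. Region counts sum to the
#' total number of distinct MLGs.
#'
#' @param isolates isolate data frame with \code{mlg_id}.
#' @param by grouping column (e.g. \code{"location"} or \code{"vintage"}).
#' @param classification optional data frame from \code{\link{classify_mlgs}}.
#' @return Data frame: region (group names joined by \code{"+"}), n_groups,
#'   n_mlgs and, with a classification, n_commercial, n_commercial_related,
#'   n_unique.
#' @export
mlg_overlap <- function(isolates, by = "location", classification = NULL) {
  if (!by %in% names(isolates)) stop("grouping column not found: ", by)
  groups <- sort(unique(as.character(isolates[[by]])))
  if (length(groups) < 2L) stop("at least 2 groups required")
  sets <- tapply(as.character(isolates[[by]]), isolates$mlg_id,
                 function(g) paste(sort(unique(g)), collapse = "+"))
  region <- as.character(sets)
  mlg_ids <- names(sets)
  tab <- table(region)
  out <- data.frame(region = names(tab),
                    n_groups = lengths(strsplit(names(tab), "+", fixed = TRUE)),
                    n_mlgs = as.integer(tab), stringsAsFactors = FALSE)
  if (!is.null(classification)) {
    cat_of <- classification$category[match(mlg_ids, classification$mlg_id)]
    for (cc in c("commercial", "commercial_related", "unique")) {
      cnt <- table(factor(region[cat_of == cc], levels = out$region))
      out[[paste0("n_", cc)]] <- as.integer(cnt)
    }
  }
  out[order(-out$n_groups, out$region), , drop = FALSE]
}
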