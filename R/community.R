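# Cumulative microbial-activity scoring and community-table normalizations:
# max-normalized five-indicator scores, fixed-depth read normalization with
# low-depth exclusion, qPCR-based bacteria/archaea projection, and rank
# aggregation with a minimum-abundance legend filter.

ACTIVITY_INDICATORS <- c("biofilm", "bacterial_qpcr", "archaeal_qpcr",
                         "organic_acids", "biocoulombs")

#' Cumulative microbial-activity scores
#'
#' Combines five indicators of microbial activity per reactor - biofilm
#' coverage (ordinal 0-5), bacterial and archaeal 16S copies (qPCR),
#' organic-acid production (mM, sum of positive deltas), and biocoulombs -
#' into a cumulative score. Each continuous indicator is normalized by its
#' maximum across all reactors (so exactly one reactor scores 1 on each
#' indicator unless the column is all zero, which scores 0 everywhere); the
#' ordinal biofilm score is divided by its scale maximum of 5. The total is
#' the sum of the five components, hence bounded in \[0, 5\].
#'
#' @param indicators data frame with columns `reactor_id` and
#'   `r paste(ACTIVITY_INDICATORS, collapse = ", ")`; continuous indicators
#'   must be >= 0, biofilm an integer 0-5.
#' @return Tibble with `reactor_id`, one column per component (each in
#'   \[0, 1\]), and `total`.
#' @export
activity_scores <- function(indicators) {
  indicators <- tibble::as_tibble(indicators)
  need <- c("reactor_id", ACTIVITY_INDICATORS)
  if (!all(need %in% names(indicators)))
    stop(sprintf("indicator table must have columns: %s",
                 paste(need, collapse = ", ")), call. = FALSE)
  if (nrow(indicators) < 1) stop("need at least one reactor", call. = FALSE)
  if (any(indicators$biofilm < 0 | indicators$biofilm > 5 |
          indicators$biofilm != round(indicators$biofilm)))
    stop("biofilm scores must be integers in 0..5", call. = FALSE)
  continuous <- setdiff(ACTIVITY_INDICATORS, "biofilm")
  for (col in continuous) {
    if (any(indicators[[col]] < 0))
      stop(sprintf("indicator '%s' must be >= 0", col), call. = FALSE)
  }
  out <- tibble::tibble(reactor_id = indicators$reactor_id)
  out$biofilm <- indicators$biofilm / 5
  for (col in continuous) {
    mx <- max(indicators[[col]])
    out[[col]] <- if (mx > 0) indicators[[col]] / mx else 0
  }
  out$total <- rowSums(out[, ACTIVITY_INDICATORS])
  out
}

#' Normalize an amplicon table to a fixed read depth
#'
#' Samples with fewer than `min_depth` reads are excluded (sequencing did not
#' reach comparable coverage); the rest are brought to exactly `target_depth`
#' reads either by proportional rescaling (default; preserves proportions
#' exactly, counts may be fractional) or by seeded subsampling without
#' replacement (integer counts, multinomial-hypergeometric noise).
#'
#' @param table an [amplicon_table()].
#' @param target_depth reads per sample after normalization (default 100000).
#' @param min_depth inclusion threshold (default `target_depth`).
#' @param method `"proportional"` or `"subsample"`.
#' @param seed integer seed for the subsampling draw (required for
#'   `"subsample"`).
#' @return List with `table` (normalized `amplicon_table`, possibly fewer
#'   samples) and `exclusions` (tibble `sample_id`, `depth`, `reason`).
#' @export
depth_normalize <- function(table, target_depth = 1e5,
                            min_depth = target_depth,
                            method = c("proportional", "subsample"),
                            seed = NULL) {
  stopifnot(inherits(table, "amplicon_table"))
  method <- match.arg(method)
  depths <- colSums(table$counts)
  low <- depths < min_depth
  exclusions <- tibble::tibble(
    sample_id = colnames(table$counts)[low],
    depth = unname(depths[low]),
    reason = sprintf("below minimum depth (%s < %s reads)",
                     format(depths[low], scientific = FALSE),
                     format(min_depth, scientific = FALSE)))
  counts <- table$counts[, !low, drop = FALSE]
  if (ncol(counts)) {
    if (method == "proportional") {
      counts <- sweep(counts, 2, colSums(counts), "/") * target_depth
    } else {
      if (is.null(seed))
        stop("subsample method needs a seed for reproducibility",
             call. = FALSE)
      counts <- with_seed_local(seed, apply(counts, 2, function(x) {
        drawn <- sample(rep.int(seq_along(x), x), size = target_depth,
                        replace = FALSE)
        tabulate(drawn, nbins = length(x))
      }))
      rownames(counts) <- rownames(table$counts)
    }
  }
  norm <- table
  norm$counts <- counts
  list(table = norm, exclusions = exclusions)
}

#' Project bacterial relative abundances onto qPCR domain proportions
#'
#' Universal-primer amplicon data can miss archaea entirely while qPCR shows
#' them dominant. This projection displays each bacterial taxon's relative
#' abundance scaled by the qPCR bacterial fraction
#' `f = bacterial / (bacterial + archaeal)` and adds a single pooled
#' archaeal block of `100 (1 - f)` percent, so the displayed abundances sum
#' to 100% while honouring the absolute domain ratio.
#'
#' @param relative_percent named numeric vector of bacterial taxon relative
#'   abundances in percent, summing to 100.
#' @param qpcr a [qpcr_result()] for the same cathode.
#' @return List with `sample_id`, `displayed_percent` (named vector),
#'   `archaeal_block_percent`, `excluded`, `reason`.
#' @export
qpcr_domain_normalize <- function(relative_percent, qpcr) {
  stopifnot(inherits(qpcr, "qpcr_result"))
  total <- qpcr$bacterial_copies_per_cm2 + qpcr$archaeal_copies_per_cm2
  if (total == 0) {
    return(list(sample_id = qpcr$reactor_id,
                displayed_percent = relative_percent * NA_real_,
                archaeal_block_percent = NA_real_,
                excluded = TRUE, reason = "no qPCR signal in either domain"))
  }
  if (abs(sum(relative_percent) - 100) > 1e-6)
    stop("bacterial relative abundances must sum to 100%", call. = FALSE)
  f <- qpcr$bacterial_copies_per_cm2 / total
  list(sample_id = qpcr$reactor_id,
       displayed_percent = relative_percent * f,
       archaeal_block_percent = 100 * (1 - f),
       excluded = FALSE, reason = NA_character_)
}

#' Aggregate an amplicon table at a taxonomic rank
#'
#' Sums ASV counts by taxon at the requested rank (unassigned lineages pooled
#' under `"NA"`), then pools taxa that never reach `min_percent` of any
#' sample's reads into `"other"`. Optionally truncates to the `top_n` taxa by
#' maximum per-sample relative abundance (the rest joins `"other"`), the
#' usual legend-size control for stacked-bar figures.
#'
#' @param table an [amplicon_table()].
#' @param rank one of `r paste(AMPLICON_RANKS, collapse = ", ")`.
#' @param min_percent legend threshold in percent (default 0 = keep all).
#' @param top_n optional cap on the number of named taxa.
#' @return Tibble: `taxon` plus one count column per sample; column sums
#'   equal the input sample depths.
#' @export
aggregate_taxa <- function(table, rank, min_percent = 0, top_n = NULL) {
  stopifnot(inherits(table, "amplicon_table"))
  if (!rank %in% AMPLICON_RANKS)
    stop(sprintf("unknown rank '%s'; use one of %s", rank,
                 paste(AMPLICON_RANKS, collapse = ", ")), call. = FALSE)
  taxon <- table$taxonomy[[rank]]
  taxon[is.na(taxon)] <- "NA"
  agg <- rowsum(table$counts, group = taxon)
  pct <- sweep(agg, 2, colSums(agg), "/") * 100
  pct[is.nan(pct)] <- 0
  keep <- apply(pct, 1, max) >= min_percent
  if (!is.null(top_n)) {
    ord <- order(apply(pct, 1, max), decreasing = TRUE)
    top <- rownames(agg)[ord][seq_len(min(top_n, nrow(agg)))]
    keep <- keep & rownames(agg) %in% top
  }
  named <- agg[keep, , drop = FALSE]
  other <- colSums(agg[!keep, , drop = FALSE])
  out <- tibble::as_tibble(named, rownames = "taxon")
  if (any(other > 0) || any(!keep))
    out <- dplyr::bind_rows(out, tibble::tibble(taxon = "other",
                                                !!!as.list(other)))
  out
}

#' Standardized indicator matrix for external ordination
#'
#' Centers and scales the continuous activity indicators to unit variance,
#' the form consumed by multi-factor analysis or other ordination tools
#' outside this package.
#'
#' @param indicators the table accepted by [activity_scores()].
#' @return Numeric matrix (reactors x indicators) with attribute
#'   `"reactor_id"`.
#' @export
indicator_matrix <- function(indicators) {
  indicators <- tibble::as_tibble(indicators)
  m <- scale(as.matrix(indicators[, ACTIVITY_INDICATORS]))
  m[is.nan(m)] <- 0
  rownames(m) <- indicators$reactor_id
  m
}
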