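#' Match trees between two dates by plantation grid position
#'
#' Trees are keyed on (row, column).  Trees present on only one date are
#' reported unmatched; pairs where either record is unreliable are kept but
#' marked `use = FALSE`, the analogue of discarding incorrectly reconstructed
#' trees from downstream statistics.
#'
#' @param records_a,records_b `tree_records` for the earlier and later date.
#' @return `list(pairs, unmatched_a, unmatched_b)`; `pairs` carries columns
#'   suffixed `_a` / `_b` plus `use`.
#' @export
match_trees <- function(records_a, records_b) {
  key <- function(r) paste(r$row, r$column, sep = ":")
  # unreliable duplicates (e.g. merged crowns that lost a node tie) are
  # dropped up front; duplicates among reliable records are a hard error
  dedup <- function(r, which) {
    k <- key(r)
    dup <- duplicated(k) | duplicated(k, fromLast = TRUE)
    r <- r[!(dup & !r$reliable), ]
    if (anyDuplicated(key(r)))
      stop("duplicate (row, column) keys on the ", which, " date")
    r
  }
  records_a <- dedup(records_a, "earlier")
  records_b <- dedup(records_b, "later")
  ka <- key(records_a); kb <- key(records_b)
  common <- intersect(ka, kb)
  a <- records_a[match(common, ka), ]
  b <- records_b[match(common, kb), ]
  pairs <- data.frame(row = a$row, column = a$column,
                      tree_id = a$tree_id, treatment = a$treatment,
                      stringsAsFactors = FALSE)
  for (cn in c("x", "y", "area_m2", "height_m", "volume_m3", "reliable", "date_label")) {
    pairs[[paste0(cn, "_a")]] <- a[[cn]]
    pairs[[paste0(cn, "_b")]] <- b[[cn]]
  }
  pairs$use <- pairs$reliable_a & pairs$reliable_b
  list(pairs = pairs,
       unmatched_a = records_a[!ka %in% common, ],
       unmatched_b = records_b[!kb %in% common, ])
}

#' Signed percent change between two dates
#'
#' `100 * (later - earlier) / earlier`: an increase is positive, a decrease
#' negative.  A non-positive baseline gives `NA` with a warning (such records
#' are excluded from summaries).
#'
#' @param value_later,value_earlier feature values (vectorized).
#' @return Percent change.
#' @export
#' @examples
#' percent_change(34.74, 44.09)  # -21.21 %
percent_change <- function(value_later, value_earlier) {
  bad <- !is.na(value_earlier) & value_earlier <= 0
  if (any(bad)) warning(sum(bad), " record(s) with non-positive baseline excluded")
  out <- 100 * (value_later - value_earlier) / value_earlier
  out[bad] <- NA_real_
  out
}

#' Per-tree change table for a date pair
#'
#' Adds per-feature deltas (later minus earlier) and signed percent changes
#' to a matched-pairs table.
#'
#' @param pairs matched pairs from [match_trees()].
#' @param comparison label for the date pair (e.g. `"impact"`, `"growth"`,
#'   `"restoration"`).
#' @return The pairs table with `d_area`, `d_height`, `d_volume`,
#'   `pct_area`, `pct_height`, `pct_volume` and `comparison` columns.
#' @export
change_table <- function(pairs, comparison = "change") {
  pairs$d_area <- pairs$area_m2_b - pairs$area_m2_a
  pairs$d_height <- pairs$height_m_b - pairs$height_m_a
  pairs$d_volume <- pairs$volume_m3_b - pairs$volume_m3_a
  pairs$pct_area <- percent_change(pairs$area_m2_b, pairs$area_m2_a)
  pairs$pct_height <- percent_change(pairs$height_m_b, pairs$height_m_a)
  pairs$pct_volume <- percent_change(pairs$volume_m3_b, pairs$volume_m3_a)
  pairs$comparison <- comparison
  pairs
}

#' Treatment-level change summary
#'
#' Per pruning treatment: mean and sample (n-1) standard deviation of the
#' per-tree deltas, the mean of the per-tree percent changes (the headline
#' percentage column), the ratio-of-means percentage (secondary), and the
#' coefficient of variation of the later-date heights.  Only pairs with
#' `use = TRUE` and a positive baseline enter.
#'
#' @param changes a [change_table()] result.
#' @return Data frame, one row per treatment x feature.
#' @export
summarize_change <- function(changes) {
  ch <- changes[changes$use, ]
  feats <- list(area = c("d_area", "pct_area", "area_m2_a", "area_m2_b"),
                height = c("d_height", "pct_height", "height_m_a", "height_m_b"),
                volume = c("d_volume", "pct_volume", "volume_m3_a", "volume_m3_b"))
  out <- list()
  for (tr in unique(ch$treatment)) {
    sub <- ch[!is.na(ch$treatment) & ch$treatment == tr, ]
    if (!nrow(sub)) { warning("empty treatment group ", tr, " omitted"); next }
    for (f in names(feats)) {
      cols <- feats[[f]]
      ok <- !is.na(sub[[cols[2]]])
      d <- sub[[cols[1]]][ok]
      out[[length(out) + 1L]] <- data.frame(
        comparison = sub$comparison[1], treatment = tr, feature = f,
        n_trees = sum(ok),
        mean_delta = mean(d),
        sd_delta = if (sum(ok) > 1) sd(d) else 0,
        mean_pct = mean(sub[[cols[2]]][ok]),
        pct_of_means = 100 * (mean(sub[[cols[4]]][ok]) - mean(sub[[cols[3]]][ok])) /
          mean(sub[[cols[3]]][ok]),
        cv_pct_later = 100 * sd(sub[[cols[4]]][ok]) / mean(sub[[cols[4]]][ok]),
        low_n = sum(ok) < 2,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Annual growth by pruning-severity class
#'
#' Pruning severity is the percent crown volume removed between the
#' pre-/post-pruning dates, `-percent_change(volume)` clipped at 0, binned
#' into the left-closed classes `[0,10) [10,30) [30,50) [50,Inf)`.  Growth is
#' the percent volume change over the following year.  Summarized per class
#' and treatment.
#'
#' @param pairs_12 matched pairs for the pruning date pair (date 1 to 2).
#' @param pairs_23 matched pairs for the growth date pair (date 2 to 3).
#' @return Data frame: class, treatment, n_trees, mean and SD of percent
#'   annual volume growth.
#' @export
severity_class_growth <- function(pairs_12, pairs_23) {
  c12 <- change_table(pairs_12)
  c23 <- change_table(pairs_23)
  k12 <- paste(c12$row, c12$column); k23 <- paste(c23$row, c23$column)
  common <- intersect(k12[c12$use & !is.na(c12$pct_volume)],
                      k23[c23$use & !is.na(c23$pct_volume)])
  a <- c12[match(common, k12), ]
  b <- c23[match(common, k23), ]
  severity <- pmax(0, -a$pct_volume)
  cls <- classify_severity(severity)
  df <- data.frame(class = cls, treatment = a$treatment, growth = b$pct_volume,
                   stringsAsFactors = FALSE)
  agg <- do.call(rbind, lapply(split(df, list(df$class, df$treatment), drop = TRUE),
                               function(s) data.frame(
                                 class = as.character(s$class[1]),
                                 treatment = s$treatment[1],
                                 n_trees = nrow(s),
                                 mean_growth_pct = mean(s$growth),
                                 sd_growth_pct = if (nrow(s) > 1) sd(s$growth) else 0,
                                 stringsAsFactors = FALSE)))
  rownames(agg) <- NULL
  agg[order(match(agg$class, levels(cls)), agg$treatment), ]
}

#' Coefficient of variation of a feature
#'
#' `100 * sample SD / mean` over a record set (e.g. the heights of
#' mechanically pruned trees on one date).
#'
#' @param records `tree_records` (or any data frame).
#' @param feature column name, e.g. `"height_m"`.
#' @return CV in percent.
#' @export
coefficient_of_variation <- function(records, feature = "height_m") {
  v <- records[[feature]]
  v <- v[!is.na(v)]
  if (!length(v)) stop("no values for feature ", feature)
  m <- mean(v)
  if (m == 0) stop("undefined CV: mean is zero")
  100 * sd(v) / m
}

#' Export a four-level feature map
#'
#' Ranks a per-tree feature (or feature delta) into `n_levels` quantile
#' classes and writes one polygon per tree with its level, for map display of
#' orchard-scale variability.
#'
#' @param records data frame with `tree_id`, `row`, `column`, `mask_label`
#'   and the feature column.
#' @param mask the [tree_mask] supplying polygons.
#' @param feature column name to rank.
#' @param path GeoJSON output path.
#' @param n_levels number of classes (default 4).
#' @return Invisibly, the records with a `level` column.
#' @export
export_level_maps <- function(records, mask, feature, path, n_levels = 4) {
  if (n_levels < 2) stop("n_levels must be at least 2")
  v <- records[[feature]]
  qs <- unique(quantile(v, probs = seq(0, 1, length.out = n_levels + 1), na.rm = TRUE))
  if (length(qs) < 3) {
    warning("feature nearly constant; all trees in level 1")
    records$level <- 1L
  } else {
    records$level <- as.integer(cut(v, qs, include.lowest = TRUE, labels = FALSE))
  }
  feats <- lapply(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    ml <- if (!is.null(r$mask_label)) r$mask_label else r$tree_id
    poly <- component_polygon(mask, ml)
    if (is.null(poly)) return(NULL)
    list(type = "Feature",
         properties = list(tree_id = r$tree_id, row = r$row, column = r$column,
                           value = unname(v[i]), level = r$level),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(poly)),
                                                   function(j) unname(poly[j, ])))))
  })
  feats <- feats[!vapply(feats, is.null, TRUE)]
  jsonlite::write_json(list(type = "FeatureCollection", feature = feature,
                            features = feats),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(records)
}
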