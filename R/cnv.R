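## Depth-based CNV detection: ratio normalization, circular binary
## segmentation (compiled kernel in src/cbs.cpp), trio copy-state calling
## and inheritance classification.
##
## Segmentation runs on LINEAR normalized depth, not log-ratio: homozygous
## deletions have depth 0, where the log is undefined.  Permutation p-values
## draw from R's RNG, so results are reproducible under set.seed().

.STATE_BREAKS <- c(hom_del = 0.25, hemi = 0.75, normal = 1.25)

#' Normalize a raw depth table
#'
#' Divides each sample's bin depths by that sample's median bin depth
#' (autosomal ratio normalization), so the per-sample median normalized
#' depth is exactly 1 and a one-copy loss sits near 0.5.
#'
#' @param d Raw depth-bin data frame ([read_depth_table()] layout).
#' @return Same data frame with the three depth columns normalized.
#' @export
normalize_depth <- function(d) {
  for (col in c("depth_father", "depth_mother", "depth_proband")) {
    med <- median(d[[col]])
    if (!is.finite(med) || med <= 0)
      .stopf("%s: median depth is not positive; cannot normalize", col)
    d[[col]] <- d[[col]] / med
  }
  d
}

#' Circular binary segmentation of one value sequence
#'
#' Recursively splits the circularized sequence at the arc maximizing the
#' pooled two-sample |t| statistic between arc and complement, accepting a
#' split when its permutation p-value is below `alpha`, and recursing into
#' the resulting pieces.  Sequences shorter than `2 * min_width` are left
#' as a single segment.
#'
#' @param values Ordered numeric values (normalized depths of one contig).
#' @param alpha Split acceptance level for the permutation test.
#' @param n_permutations Number of value shuffles per tested split.
#' @param min_width Minimum number of points in any resulting segment.
#' @return Sorted integer changepoints: `c` means a boundary between
#'   positions `c` and `c + 1`; empty when no split is significant.
#' @export
segment_cbs <- function(values, alpha = 0.01, n_permutations = 1000L,
                        min_width = 3L) {
  stopifnot(is.numeric(values), min_width >= 1L)
  cps <- integer()
  recurse <- function(lo, hi) {
    m <- hi - lo + 1L
    if (m < 2L * min_width) return(invisible())
    x <- values[lo:hi]
    b <- .cbs_best_split(x, min_width)
    if (b$i < 0L || b$t <= 0) return(invisible())
    p <- .cbs_perm_pvalue(x, b$t, as.integer(n_permutations), alpha,
                          as.integer(min_width))
    if (p >= alpha) return(invisible())
    i <- b$i; j <- b$j                      # 0-based arc (i, j] within x
    if (i > 0L) cps <<- c(cps, lo + i - 1L)
    if (j < m) cps <<- c(cps, lo + j - 1L)
    if (i > 0L) recurse(lo, lo + i - 1L)
    recurse(lo + i, lo + j - 1L)
    if (j < m) recurse(lo + j, hi)
  }
  recurse(1L, length(values))
  sort(unique(cps))
}

#' Segment a trio depth table
#'
#' Runs [segment_cbs()] per sample on each contig's bin sequence and builds
#' consensus segments from the union of per-sample changepoints (the three
#' samples share one bin grid, so shared deletion boundaries line up).
#'
#' @param d Normalized depth-bin data frame (see [normalize_depth()]).
#' @param alpha,n_permutations,min_width Passed to [segment_cbs()].
#' @return Data frame of consensus segments: `contig`, `start`, `end` (bp,
#'   0-based half-open), `n_bins`, and per-sample mean normalized depth.
#' @export
segment_trio <- function(d, alpha = 0.01, n_permutations = 1000L,
                         min_width = 3L) {
  cols <- c("depth_father", "depth_mother", "depth_proband")
  out <- NULL
  for (ct in unique(d$contig)) {
    dc <- d[d$contig == ct, , drop = FALSE]
    dc <- dc[order(dc$start), , drop = FALSE]
    nb <- nrow(dc)
    cps <- integer()
    for (col in cols)
      cps <- union(cps, segment_cbs(dc[[col]], alpha = alpha,
                                    n_permutations = n_permutations,
                                    min_width = min_width))
    bounds <- c(0L, sort(cps), nb)
    for (s in seq_len(length(bounds) - 1L)) {
      rows <- (bounds[s] + 1L):bounds[s + 1L]
      out <- rbind(out, data.frame(
        contig = ct,
        start = dc$start[rows[1]],
        end = dc$end[rows[length(rows)]],
        n_bins = length(rows),
        mean_father = mean(dc$depth_father[rows]),
        mean_mother = mean(dc$depth_mother[rows]),
        mean_proband = mean(dc$depth_proband[rows]),
        stringsAsFactors = FALSE))
    }
  }
  rownames(out) <- NULL
  out
}

#' @noRd
depth_state <- function(m) {
  ifelse(m < .STATE_BREAKS["hom_del"], "hom_del",
    ifelse(m < .STATE_BREAKS["hemi"], "hemi",
      ifelse(m < .STATE_BREAKS["normal"], "normal", "gain")))
}

#' Call trio copy states on consensus segments
#'
#' Classifies each sample's mean normalized depth per segment into
#' `hom_del` (< 0.25), `hemi` ([0.25, 0.75)), `normal` ([0.75, 1.25)) or
#' `gain` (>= 1.25), then merges adjacent segments whose trio state vector
#' is identical (bin-weighted means).
#'
#' @param segments Output of [segment_trio()].
#' @return Segments with `state_father`, `state_mother`, `state_proband`.
#' @export
call_copy_states <- function(segments) {
  s <- segments
  s$state_father <- unname(depth_state(s$mean_father))
  s$state_mother <- unname(depth_state(s$mean_mother))
  s$state_proband <- unname(depth_state(s$mean_proband))
  ## merge adjacent same-state segments per contig
  out <- NULL
  for (ct in unique(s$contig)) {
    sc <- s[s$contig == ct, , drop = FALSE]
    sc <- sc[order(sc$start), , drop = FALSE]
    key <- paste(sc$state_father, sc$state_mother, sc$state_proband)
    grp <- cumsum(c(TRUE, key[-1] != key[-length(key)]))
    for (g in unique(grp)) {
      rows <- which(grp == g)
      w <- sc$n_bins[rows]
      out <- rbind(out, data.frame(
        contig = ct,
        start = sc$start[rows[1]],
        end = sc$end[rows[length(rows)]],
        n_bins = sum(w),
        mean_father = sum(sc$mean_father[rows] * w) / sum(w),
        mean_mother = sum(sc$mean_mother[rows] * w) / sum(w),
        mean_proband = sum(sc$mean_proband[rows] * w) / sum(w),
        state_father = sc$state_father[rows[1]],
        state_mother = sc$state_mother[rows[1]],
        state_proband = sc$state_proband[rows[1]],
        stringsAsFactors = FALSE))
    }
  }
  rownames(out) <- NULL
  out
}

#' Classify segment inheritance
#'
#' Explicit rule replacing manual review: proband homozygous deletion with
#' both parents hemizygous is `inherited_recessive`; a proband loss
#' (`hom_del` or `hemi`) with both parents normal is `de_novo`; anything
#' else is `other`.
#'
#' @param segments Output of [call_copy_states()].
#' @return Segments with an `inheritance` column.
#' @export
classify_inheritance <- function(segments) {
  s <- segments
  parents_hemi <- s$state_father == "hemi" & s$state_mother == "hemi"
  parents_norm <- s$state_father == "normal" & s$state_mother == "normal"
  child_loss <- s$state_proband %in% c("hom_del", "hemi")
  s$inheritance <- ifelse(s$state_proband == "hom_del" & parents_hemi,
                          "inherited_recessive",
                   ifelse(child_loss & parents_norm, "de_novo", "other"))
  s
}
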