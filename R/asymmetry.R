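#' Bounded interhemispheric asymmetry indices
#'
#' `lc()` is the laterality coefficient: the contrast of one task's signed
#' response amplitude between the contralateral and ipsilateral homotopic
#' channels,
#' `LC = (R_contra - R_ipsi) / sqrt(2 (R_contra^2 + R_ipsi^2))`.
#' `trac()` is the task response asymmetry coefficient: the identical
#' normalization applied to one channel's responses to contralateral-hand
#' versus ipsilateral-hand motor imagery. Both are bounded in [-1, 1] for
#' any finite signed inputs (equality exactly when the responses are
#' opposite, `b = -a != 0`), are antisymmetric in their arguments, flip
#' sign under joint negation, and are invariant under joint positive
#' rescaling. The all-zero case returns 0 by convention.
#'
#' The two functions share the formula; the semantic difference (one task
#' across two channels vs two tasks on one channel) lives in the caller's
#' data wiring, done by [compute_asymmetry_table()].
#'
#' @param a,b Signed response amplitudes (vectors recycle).
#' @return Numeric vector of index values in [-1, 1].
#' @examples
#' lc(1, 0)    # 1/sqrt(2)
#' lc(1, -1)   # 1
#' trac(0, 0)  # 0
#' @export
lc <- function(a, b) {
  if (any(!is.finite(a)) || any(!is.finite(b)))
    stop_invalid("asymmetry index inputs must be finite")
  d <- sqrt(2 * (a^2 + b^2))
  v <- ifelse(d == 0, 0, (a - b) / d)
  # the bound is exact mathematically; guard against 1-ulp rounding excess
  pmin(pmax(v, -1), 1)
}

#' @rdname lc
#' @export
trac <- lc

#' Reconstructed legacy laterality formulas
#'
#' Three laterality normalizations reconstructed from the prior literature
#' for signed NIRS response amplitudes, each exhibiting a documented
#' failure mode, plus the negative-coefficient-zeroing workaround:
#' \describe{
#'   \item{`eq1`}{`(|a| - |b|) / (|a| + |b|)` - insensitive to response
#'     polarity (joint sign flips are invisible).}
#'   \item{`eq2`}{`(a - b) / (|a| + |b|)` - saturates at exactly +/-1
#'     whenever the two responses have opposite signs, regardless of
#'     magnitude.}
#'   \item{`eq3`}{`(a - b) / (a + b)` - unbounded; singular when the
#'     denominator vanishes (opposite responses).}
#'   \item{`eq3_zeroed`}{`eq3` after replacing negative inputs with zero
#'     (discards polarity information).}
#' }
#' These are reconstructions: chosen as the simplest standard laterality
#' forms reproducing each failure mode, and labeled as such in outputs.
#' Division by zero yields an overflow-flagged sentinel (`Inf` with the
#' numerator's sign, or 0 when the numerator is also zero), never an
#' error.
#'
#' @param a,b Signed response amplitudes.
#' @param variant One of `"eq1"`, `"eq2"`, `"eq3"`, `"eq3_zeroed"`.
#' @return Numeric vector with logical attribute `"overflow"` marking
#'   singular denominators.
#' @export
alt_laterality <- function(a, b, variant = c("eq1", "eq2", "eq3", "eq3_zeroed")) {
  variant <- match.arg(variant)
  if (any(!is.finite(a)) || any(!is.finite(b)))
    stop_invalid("asymmetry index inputs must be finite")
  if (variant == "eq3_zeroed") {
    a <- pmax(a, 0); b <- pmax(b, 0)
  }
  num <- switch(variant, eq1 = abs(a) - abs(b), a - b)
  den <- switch(variant, eq1 = , eq2 = abs(a) + abs(b), a + b)
  overflow <- den == 0 & num != 0
  v <- ifelse(den == 0,
              ifelse(num == 0, 0, sign(num) * Inf),
              num / den)
  attr(v, "overflow") <- overflow
  v
}

#' Numerical-stability summary of an index distribution
#'
#' Quantifies the saturation and blow-up behavior of a set of asymmetry
#' values: the fraction sitting exactly at +/-1 (within `tol`), the
#' fraction exceeding 0.99 in absolute value, and the 95th percentile and
#' maximum of the absolute values. Overflowed (singular-denominator)
#' values count as `Inf` in the maximum and are tallied separately.
#'
#' @param values Numeric index values (may contain `Inf` sentinels).
#' @param overflow Optional logical vector flagging singular values, e.g.
#'   `attr(x, "overflow")` from [alt_laterality()].
#' @param tol Absolute tolerance for "reached 1 or -1".
#' @return A `stability_report` list: `frac_at_unity`, `frac_above_099`,
#'   `p95_abs`, `max_abs`, `n`, `n_overflow`.
#' @export
stability_report <- function(values, overflow = NULL, tol = 1e-12) {
  overflow <- overflow %||% attr(values, "overflow") %||%
    rep(FALSE, length(values))
  if (length(values) == 0) stop_invalid("empty input")
  av <- abs(as.numeric(values))
  av[overflow] <- Inf
  structure(list(frac_at_unity = mean(abs(av - 1) <= tol & is.finite(av)),
                 frac_above_099 = mean(av > 0.99),
                 p95_abs = as.numeric(stats::quantile(av, 0.95, names = FALSE)),
                 max_abs = max(av),
                 n = length(av),
                 n_overflow = sum(overflow)),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf(paste0("<stability_report> n=%d: %.1f%% at +/-1, %.1f%% ",
                     "with |v|>0.99, p95 |v|=%.3g, max |v|=%.3g, ",
                     "%d overflow\n"),
              x$n, 100 * x$frac_at_unity, 100 * x$frac_above_099,
              x$p95_abs, x$max_abs, x$n_overflow))
  invisible(x)
}

# hand label -> canonical hand side. Patients are analyzed in the
# lesion-referenced frame (after mirroring the lesioned hemisphere maps to
# left-side channel labels, so the affected hand is the right hand).
hand_side <- function(task) {
  side <- c(mi_left = "left", mi_right = "right",
            affected = "right", intact = "left")[task]
  if (anyNA(side)) stop_invalid("unknown task label(s): ",
                                paste(unique(task[is.na(side)]), collapse = ", "))
  unname(side)
}

# hemisphere label presented in output tables
hemisphere_label <- function(hemi, patient) {
  if (patient) c(left = "lesioned", right = "intact")[hemi] else hemi
}

#' Compute the per-session asymmetry table
#'
#' Wires response amplitudes into the LC and TRAC indices (and optionally
#' the reconstructed legacy formulas, computed on the same hemispheric
#' wiring as LC). Per homotopic pair and hand, LC contrasts the
#' contralateral against the ipsilateral channel's response to that hand's
#' motor imagery; per channel, TRAC contrasts the channel's responses to
#' contralateral-hand versus ipsilateral-hand motor imagery. Patients'
#' responses must already be mirrored ([mirror_responses()]), so their
#' task labels are `affected`/`intact` and left-side channels denote the
#' lesioned hemisphere; healthy subjects keep `mi_left`/`mi_right` and
#' literal hemispheres.
#'
#' @param responses Tibble with columns `channel`, `task`, `chromophore`,
#'   `coefficient`; optional grouping columns `subject`, `group`,
#'   `session_id`, `day_index` are carried through.
#' @param montage The montage the channels belong to.
#' @param kinds Index kinds to compute: subset of `"LC"`, `"TRAC"`,
#'   `"alt1"`, `"alt2"`, `"alt3"`, `"alt3_zeroed"`.
#' @return Tidy tibble: grouping columns, `pair`, `channel` (NA for
#'   pair-level indices), `hand` (NA for TRAC), `hemisphere` (NA for
#'   pair-level indices), `chromophore`, `index_kind`, `value`,
#'   `overflow`. Units with a missing task coefficient are skipped with a
#'   warning.
#' @export
compute_asymmetry_table <- function(responses, montage,
                                    kinds = c("LC", "TRAC")) {
  allowed <- c("LC", "TRAC", "alt1", "alt2", "alt3", "alt3_zeroed")
  if (!all(kinds %in% allowed))
    stop_invalid("unknown index kind(s): ",
                 paste(setdiff(kinds, allowed), collapse = ", "))
  grp_cols <- intersect(c("subject", "group", "session_id", "day_index"),
                        names(responses))
  if (length(grp_cols) == 0)
    return(asymmetry_one(responses, montage, kinds))
  keys <- unique(responses[grp_cols])
  res <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- dplyr::inner_join(responses, keys[i, , drop = FALSE],
                             by = grp_cols)
    one <- asymmetry_one(sub, montage, kinds)
    if (nrow(one) && length(grp_cols))
      one <- dplyr::bind_cols(keys[rep(i, nrow(one)), , drop = FALSE], one)
    one
  })
  dplyr::bind_rows(res)
}

# asymmetry table for a single subject x session block
asymmetry_one <- function(responses, montage, kinds) {
  tasks <- unique(responses$task)
  patient <- any(tasks %in% c("affected", "intact"))
  hemi <- setNames(montage$channels$hemisphere, montage$channels$channel)
  pair_of <- pair_of_channel(montage)
  look <- setNames(responses$coefficient,
                   paste(responses$channel, responses$task,
                         responses$chromophore))
  chroms <- unique(responses$chromophore)
  out <- list()

  pair_kinds <- intersect(kinds, c("LC", "alt1", "alt2", "alt3", "alt3_zeroed"))
  if (length(pair_kinds)) {
    grid <- expand.grid(pair_idx = seq_len(nrow(montage$pairs)),
                        task = tasks, chromophore = chroms,
                        stringsAsFactors = FALSE)
    chL <- montage$pairs$left_channel[grid$pair_idx]
    chR <- montage$pairs$right_channel[grid$pair_idx]
    side <- hand_side(grid$task)
    contra_ch <- ifelse(side == "left", chR, chL)
    ipsi_ch <- ifelse(side == "left", chL, chR)
    a <- look[paste(contra_ch, grid$task, grid$chromophore)]
    b <- look[paste(ipsi_ch, grid$task, grid$chromophore)]
    ok <- !is.na(a) & !is.na(b)
    if (any(!ok))
      warning(sum(!ok), " pair/task/chromophore unit(s) skipped: missing ",
              "task coefficient", call. = FALSE)
    for (kind in pair_kinds) {
      v <- if (kind == "LC") lc(a[ok], b[ok])
      else alt_laterality(a[ok], b[ok], sub("^alt", "eq", kind))
      out[[length(out) + 1L]] <- tibble::tibble(
        pair = montage$pairs$pair[grid$pair_idx[ok]],
        channel = NA_character_,
        hand = grid$task[ok],
        hemisphere = NA_character_,
        chromophore = grid$chromophore[ok],
        index_kind = kind,
        value = as.numeric(v),
        overflow = attr(v, "overflow") %||% rep(FALSE, sum(ok)))
    }
  }

  if ("TRAC" %in% kinds) {
    paired_ch <- names(pair_of)
    grid <- expand.grid(channel = intersect(unique(responses$channel),
                                            montage$channels$channel),
                        chromophore = chroms, stringsAsFactors = FALSE)
    ch_side <- hemi[grid$channel]
    if (length(tasks) != 2)
      stop_invalid("TRAC needs exactly two task levels, got: ",
                   paste(tasks, collapse = ", "))
    sides <- hand_side(tasks)
    contra_task <- ifelse(ch_side == "left", tasks[sides == "right"],
                          tasks[sides == "left"])
    ipsi_task <- ifelse(ch_side == "left", tasks[sides == "left"],
                        tasks[sides == "right"])
    a <- look[paste(grid$channel, contra_task, grid$chromophore)]
    b <- look[paste(grid$channel, ipsi_task, grid$chromophore)]
    ok <- !is.na(a) & !is.na(b)
    if (any(!ok))
      warning(sum(!ok), " channel/chromophore unit(s) skipped: missing ",
              "task coefficient", call. = FALSE)
    out[[length(out) + 1L]] <- tibble::tibble(
      pair = unname(pair_of[grid$channel[ok]]),
      channel = grid$channel[ok],
      hand = NA_character_,
      hemisphere = unname(hemisphere_label(ch_side[ok], patient)),
      chromophore = grid$chromophore[ok],
      index_kind = "TRAC",
      value = as.numeric(trac(a[ok], b[ok])),
      overflow = FALSE)
  }
  dplyr::bind_rows(out)
}
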