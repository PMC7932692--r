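#' Pair ensembles of aligned lineages
#'
#' A `pair_ensemble` holds aligned cell pairs of one type together with the
#' `cycle_set` they index into:
#' * `SC` (sister cells): the two daughters of one mother, aligned at the
#'   division that created them;
#' * `NC` (neighbor cells): co-trapped, non-sibling lineages aligned at a
#'   frame where both start a new cycle with nearly identical birth lengths;
#' * `RP` (random pairs): lineages from different traps aligned artificially
#'   at a cycle start.
#'
#' Each member's `t0` is the absolute time of its alignment cycle start and
#' `g0` the lineage generation index of that cycle; pair generation `g`
#' (1-based) maps to lineage generation `g0 + g - 1`.
#'
#' @name pair_ensemble
NULL

new_pair_ensemble <- function(type, pairs, cs) {
  structure(list(pair_type = type, pairs = pairs, cs = cs, n = nrow(pairs)),
            class = "pair_ensemble")
}

#' @export
print.pair_ensemble <- function(x, ...) {
  cat(sprintf("<pair_ensemble> type %s, %d pairs\n", x$pair_type, x$n))
  invisible(x)
}

#' Number of pairs in an ensemble
#' @param ensemble A `pair_ensemble`.
#' @return Integer count.
#' @export
n_pairs <- function(ensemble) ensemble$n

#' Subset or resample the pairs of an ensemble
#'
#' Index with repetition allowed (used by the bootstrap).
#'
#' @param ensemble A `pair_ensemble`.
#' @param idx Integer indices into the pair list.
#' @return A `pair_ensemble` with the selected pairs.
#' @export
subset_pairs <- function(ensemble, idx) {
  p <- ensemble$pairs[idx, , drop = FALSE]
  rownames(p) <- NULL
  new_pair_ensemble(ensemble$pair_type, p, ensemble$cs)
}

#' Build sister-cell pairs
#'
#' Emits one pair for every mother whose two daughters are both tracked (in
#' sisters-machine data, the founding division of each trap: the two tip
#' lineages' root cycles share a parent). `t=0` is the shared division;
#' generation 1 is each daughter's first full cycle.
#'
#' @param cs A `cycle_set` from [segment_cycles()].
#' @return A `pair_ensemble` of type `"SC"`.
#' @export
build_sc_pairs <- function(cs) {
  cy <- cs$cycles
  roots <- cy[!(cy$parent_id %in% cy$cell_id) & !is.na(cy$lineage_id), ,
              drop = FALSE]
  by_mother <- split(seq_len(nrow(roots)), roots$parent_id)
  by_mother <- by_mother[vapply(by_mother, length, integer(1)) == 2L]
  rows <- lapply(by_mother, function(ii) {
    a <- roots[ii[1], ]
    b <- roots[ii[2], ]
    data.frame(lineage_a = a$lineage_id, lineage_b = b$lineage_id,
               g0_a = a$gen, g0_b = b$gen,
               t0_a = a$birth_time, t0_b = b$birth_time,
               trap_a = a$trap_id, trap_b = b$trap_id,
               stringsAsFactors = FALSE)
  })
  pairs <- if (length(rows)) do.call(rbind, rows) else empty_pairs()
  rownames(pairs) <- NULL
  if (nrow(pairs)) pairs <- cbind(pair_id = sprintf("SC%04d", seq_len(nrow(pairs))), pairs,
                                  stringsAsFactors = FALSE)
  new_pair_ensemble("SC", pairs, cs)
}

#' Build neighbor-cell pairs
#'
#' Scans each trap's two co-resident, non-sibling tip lineages for frames
#' where both begin a new cycle within `div_sync_tol` frames and with birth
#' lengths differing by less than `len_tol_rel` of their mean. The sibling
#' alignment (the two root cycles, which share a mother) is excluded. At most
#' one pair is taken per trap per non-overlapping epoch of `epoch_gens` mean
#' generation times, so neighbor pairs sample alignment origins across the
#' whole movie.
#'
#' @param cs A `cycle_set`.
#' @param div_sync_tol Division synchrony tolerance in frames (default 1:
#'   cycle starts within one 3-min frame of each other, the division-timing
#'   resolution of the imaging cadence).
#' @param len_tol_rel Relative birth-length tolerance (default 0.05).
#' @param epoch_gens Epoch length in mean generation times (default 6).
#' @param min_align_gen,max_align_gen Window of lineage generations within
#'   which the alignment cycle may start (defaults 5 and 13). Neighbor
#'   tracking is initiated early in the movie, as soon as a qualifying
#'   synchronous division occurs; capping the window keeps the ensemble's
#'   alignment origins comparable across datasets.
#' @return A `pair_ensemble` of type `"NC"`; traps with no qualifying
#'   alignment contribute no pair.
#' @export
build_nc_pairs <- function(cs, div_sync_tol = 1, len_tol_rel = 0.05,
                           epoch_gens = 6, min_align_gen = 5,
                           max_align_gen = 13) {
  cy <- cs$cycles[!is.na(cs$cycles$lineage_id), , drop = FALSE]
  if (!nrow(cy)) return(new_pair_ensemble("NC", empty_pairs(TRUE), cs))
  dt <- infer_dt(cs)
  tbar <- mean(cy$T)
  epoch_len <- epoch_gens * tbar
  rows <- list()
  for (tr in unique(cy$trap_id)) {
    sub <- cy[cy$trap_id == tr, , drop = FALSE]
    lins <- unique(sub$lineage_id)
    if (length(lins) != 2) next
    a <- sub[sub$lineage_id == lins[1], , drop = FALSE]
    b <- sub[sub$lineage_id == lins[2], , drop = FALSE]
    # all candidate alignments, in time order
    cand <- NULL
    for (i in seq_len(nrow(a))) {
      if (a$gen[i] < min_align_gen || a$gen[i] > max_align_gen) next
      dt_frames <- abs(b$birth_time - a$birth_time[i]) / dt
      ok <- which(dt_frames <= div_sync_tol + 1e-9)
      ok <- ok[b$gen[ok] >= min_align_gen & b$gen[ok] <= max_align_gen]
      for (j in ok) {
        if (a$gen[i] == 1L && b$gen[j] == 1L) next  # sisters, not neighbors
        mean_len <- (a$L_birth[i] + b$L_birth[j]) / 2
        if (abs(a$L_birth[i] - b$L_birth[j]) >= len_tol_rel * mean_len) next
        cand <- rbind(cand, data.frame(
          t_al = min(a$birth_time[i], b$birth_time[j]),
          i = i, j = j, stringsAsFactors = FALSE))
      }
    }
    if (is.null(cand)) next
    cand <- cand[order(cand$t_al), , drop = FALSE]
    t_start <- min(sub$birth_time)
    taken_epochs <- integer(0)
    for (k in seq_len(nrow(cand))) {
      ep <- floor((cand$t_al[k] - t_start) / epoch_len)
      if (ep %in% taken_epochs) next
      taken_epochs <- c(taken_epochs, ep)
      i <- cand$i[k]; j <- cand$j[k]
      rows[[length(rows) + 1L]] <- data.frame(
        lineage_a = lins[1], lineage_b = lins[2],
        g0_a = a$gen[i], g0_b = b$gen[j],
        t0_a = a$birth_time[i], t0_b = b$birth_time[j],
        trap_a = tr, trap_b = tr, stringsAsFactors = FALSE)
    }
  }
  pairs <- if (length(rows)) do.call(rbind, rows) else empty_pairs()
  rownames(pairs) <- NULL
  if (nrow(pairs)) pairs <- cbind(pair_id = sprintf("NC%04d", seq_len(nrow(pairs))), pairs,
                                  stringsAsFactors = FALSE)
  new_pair_ensemble("NC", pairs, cs)
}

#' Build random cross-trap pairs
#'
#' Samples unordered pairs of lineages from distinct traps, without
#' replacement, and aligns each member artificially at the start of a
#' (seeded-random) cycle. Deterministic given `seed`.
#'
#' @param cs A `cycle_set`.
#' @param n_pairs Number of pairs requested.
#' @param seed RNG seed.
#' @param align `"random"` picks the alignment cycle uniformly from the first
#'   half of each lineage (leaving room for post-alignment generations);
#'   `"first"` aligns at generation 1.
#' @return A `pair_ensemble` of type `"RP"`.
#' @export
build_rp_pairs <- function(cs, n_pairs, seed = 1, align = c("random", "first")) {
  align <- match.arg(align)
  cy <- cs$cycles[!is.na(cs$cycles$lineage_id), , drop = FALSE]
  lin <- unique(cy[, c("lineage_id", "trap_id")])
  if (length(unique(lin$trap_id)) < 2) {
    stop("build_rp_pairs: need lineages from at least 2 traps", call. = FALSE)
  }
  combos <- utils::combn(nrow(lin), 2)
  cross <- combos[, lin$trap_id[combos[1, ]] != lin$trap_id[combos[2, ]],
                  drop = FALSE]
  if (n_pairs > ncol(cross)) {
    stop("build_rp_pairs: requested ", n_pairs, " pairs but only ",
         ncol(cross), " distinct cross-trap combinations exist", call. = FALSE)
  }
  withr_seed <- function(expr) {  # local seeded draw, restoring RNG state
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
    expr
  }
  picks <- withr_seed({
    sel <- sample(ncol(cross), n_pairs)
    gsel <- stats::runif(2 * n_pairs)
    list(sel = sel, gsel = gsel)
  })
  rows <- lapply(seq_len(n_pairs), function(k) {
    ia <- cross[1, picks$sel[k]]
    ib <- cross[2, picks$sel[k]]
    mk <- function(i, u) {
      sub <- cy[cy$lineage_id == lin$lineage_id[i], , drop = FALSE]
      sub <- sub[order(sub$gen), , drop = FALSE]
      gmax <- max(1L, floor(nrow(sub) / 2))
      g0 <- if (align == "first") 1L else 1L + floor(u * gmax)
      sub[sub$gen == g0, , drop = FALSE]
    }
    a <- mk(ia, picks$gsel[2 * k - 1])
    b <- mk(ib, picks$gsel[2 * k])
    data.frame(lineage_a = a$lineage_id, lineage_b = b$lineage_id,
               g0_a = a$gen, g0_b = b$gen,
               t0_a = a$birth_time, t0_b = b$birth_time,
               trap_a = a$trap_id, trap_b = b$trap_id,
               stringsAsFactors = FALSE)
  })
  pairs <- do.call(rbind, rows)
  pairs <- cbind(pair_id = sprintf("RP%04d", seq_len(nrow(pairs))), pairs,
                 stringsAsFactors = FALSE)
  new_pair_ensemble("RP", pairs, cs)
}

empty_pairs <- function(with_id = FALSE) {
  p <- data.frame(lineage_a = character(), lineage_b = character(),
                  g0_a = integer(), g0_b = integer(),
                  t0_a = numeric(), t0_b = numeric(),
                  trap_a = character(), trap_b = character(),
                  stringsAsFactors = FALSE)
  if (with_id) p <- cbind(pair_id = character(), p, stringsAsFactors = FALSE)
  p
}

infer_dt <- function(cs) {
  fr <- cs$frames
  sel <- which(!is.na(fr$cycle_id) & fr$cycle_id == fr$cycle_id[1])
  d <- diff(fr$time_min[sel])
  if (!length(d)) 3 else stats::median(d)
}

#' Write a pair manifest as TSV
#'
#' @param ensemble A `pair_ensemble`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pair_manifest <- function(ensemble, path) {
  m <- ensemble$pairs
  m$pair_type <- ensemble$pair_type
  utils::write.table(m, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Per-pair member property values at pair generation g (1-based).
# Returns a 2-column matrix (a, b) with NA where the generation is missing.
pair_gen_property <- function(ensemble, property, g) {
  cy <- ensemble$cs$cycles
  key <- paste(cy$lineage_id, cy$gen)
  p <- ensemble$pairs
  ia <- match(paste(p$lineage_a, p$g0_a + g - 1L), key)
  ib <- match(paste(p$lineage_b, p$g0_b + g - 1L), key)
  cbind(a = cy[[property]][ia], b = cy[[property]][ib])
}
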