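# Argos pre-filtering: discard invalid class-Z locations, then remove fixes
# implying travel faster than a whale can swim (12 km/h for humpbacks),
# before any state-space modelling.

#' Drop class-Z Argos locations
#'
#' Class Z marks invalid Argos fixes; they are removed outright before speed
#' filtering. Input order is preserved.
#'
#' @param fixes data.frame with at least columns `ptt`, `time_h`, `lc`,
#'   `lon`, `lat`; `lc` must be one of 3,2,1,0,A,B,Z.
#' @return list with `fixes` (Z-free) and `n_removed`.
#' @export
drop_lc_z <- function(fixes) {
  lc <- as.character(fixes$lc)
  bad <- !(lc %in% ARGOS_CLASSES)
  if (any(bad)) {
    stop("unknown location class in record(s) ",
         paste(which(bad), collapse = ", "), ": ",
         paste(unique(lc[bad]), collapse = ", "))
  }
  keep <- lc != "Z"
  list(fixes = fixes[keep, , drop = FALSE], n_removed = sum(!keep))
}

# Speeds (km/h) between consecutive fixes; zero time gap => +Inf, which the
# filter must resolve (after the duplicate-timestamp rule).
consecutive_speeds <- function(fixes) {
  n <- nrow(fixes)
  if (n < 2) return(numeric(0))
  d <- leg_lengths_km(fixes$lon, fixes$lat)
  dt <- diff(fixes$time_h)
  sp <- ifelse(dt > 0, d / dt, ifelse(d > 0, Inf, 0))
  sp
}

#' Speed-filter a single whale's fixes
#'
#' Removes locations implying travel faster than `vmax_kmh` between
#' consecutive fixes, keeping as many fixes as possible: the retained set
#' is a maximum-size subsequence in which every consecutive retained pair
#' implies a speed at or below the threshold (found by dynamic programming
#' over the feasible-pairs graph, which is equivalent to exhaustive search
#' over deletion subsets). Among equally large retained sets the later
#' fixes are preferred, making the result deterministic. First and last
#' fixes may be removed like any other. Duplicate timestamps with
#' differing positions keep the more accurate location class (earlier in
#' 3,2,1,0,A,B) with a warning.
#'
#' @param fixes time-sorted data.frame for one ptt (no class Z).
#' @param vmax_kmh speed threshold, km/h (12 for humpback whales).
#' @return list with `fixes` (retained, time-sorted) and `removed`
#'   (the deleted rows).
#' @export
speed_filter <- function(fixes, vmax_kmh = 12) {
  stopifnot(nrow(fixes) >= 2, !is.unsorted(fixes$time_h))
  if (length(unique(fixes$ptt)) > 1) {
    stop("speed_filter expects fixes of a single ptt")
  }
  removed <- fixes[0, , drop = FALSE]

  # duplicate timestamps: keep the best LC, drop the rest
  dup <- duplicated(fixes$time_h) | duplicated(fixes$time_h, fromLast = TRUE)
  if (any(dup)) {
    rank_lc <- match(as.character(fixes$lc), ARGOS_CLASSES)
    keep <- rep(TRUE, nrow(fixes))
    for (tt in unique(fixes$time_h[dup])) {
      idx <- which(fixes$time_h == tt)
      if (length(unique(paste(fixes$lon[idx], fixes$lat[idx]))) > 1) {
        warning("duplicate timestamp with differing positions at t=", tt,
                "; keeping the most accurate location class")
      }
      best <- idx[order(rank_lc[idx])][1]
      keep[setdiff(idx, best)] <- FALSE
    }
    removed <- rbind(removed, fixes[!keep, , drop = FALSE])
    fixes <- fixes[keep, , drop = FALSE]
  }

  n <- nrow(fixes)
  if (n >= 2) {
    # longest feasible subsequence: L[i] = size of the largest retained set
    # ending at fix i, over predecessors j with speed(j, i) <= vmax
    L <- rep(1L, n)
    pred <- rep(0L, n)
    for (i in 2:n) {
      j <- seq_len(i - 1)
      d <- great_circle_km(fixes$lon[j], fixes$lat[j],
                           fixes$lon[i], fixes$lat[i])
      dt <- fixes$time_h[i] - fixes$time_h[j]
      sp <- ifelse(dt > 0, d / dt, ifelse(d > 0, Inf, 0))
      ok <- which(sp <= vmax_kmh)
      if (length(ok) > 0) {
        best <- max(L[ok])
        L[i] <- best + 1L
        pred[i] <- max(ok[L[ok] == best])  # tie -> later predecessor
      }
    }
    end <- max(which(L == max(L)))         # tie -> later endpoint
    keep <- integer(0)
    i <- end
    while (i > 0) {
      keep <- c(i, keep)
      i <- pred[i]
    }
    removed <- rbind(removed, fixes[-keep, , drop = FALSE])
    fixes <- fixes[keep, , drop = FALSE]
  }
  rownames(fixes) <- NULL
  rownames(removed) <- NULL
  list(fixes = fixes, removed = removed)
}

#' Filter a multi-whale Argos table
#'
#' Applies [drop_lc_z()] then [speed_filter()] per ptt and returns the
#' cleaned table together with a bookkeeping report of the kind tracking
#' studies publish ("N locations were received of which M were retained").
#'
#' @param fixes raw fixes data.frame (`ptt`, `time_h`, `lc`, `lon`, `lat`).
#' @param vmax_kmh speed threshold, km/h.
#' @return list with `fixes` (retained) and `report` (a `filter_report`:
#'   `n_input`, `n_removed_lcz`, `n_removed_speed`, `n_retained`).
#' @export
filter_argos <- function(fixes, vmax_kmh = 12) {
  ord <- order(fixes$ptt, fixes$time_h)
  fixes <- fixes[ord, , drop = FALSE]
  nz <- drop_lc_z(fixes)
  parts <- split(nz$fixes, nz$fixes$ptt)
  filtered <- lapply(parts, function(f) {
    if (nrow(f) < 2) return(list(fixes = f, removed = f[0, , drop = FALSE]))
    speed_filter(f, vmax_kmh)
  })
  kept <- do.call(rbind, lapply(filtered, `[[`, "fixes"))
  rownames(kept) <- NULL
  n_speed <- sum(vapply(filtered, function(x) nrow(x$removed), 0L))
  report <- structure(list(n_input = nrow(fixes),
                           n_removed_lcz = nz$n_removed,
                           n_removed_speed = as.integer(n_speed),
                           n_retained = nrow(kept)),
                      class = "filter_report")
  stopifnot(report$n_input ==
    report$n_removed_lcz + report$n_removed_speed + report$n_retained)
  list(fixes = kept, report = report)
}

#' @export
format.filter_report <- function(x, ...) {
  sprintf("%d locations received; %d class-Z removed, %d speed-filtered, %d retained",
          x$n_input, x$n_removed_lcz, x$n_removed_speed, x$n_retained)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}
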