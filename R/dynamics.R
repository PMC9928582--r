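#' Count trans and cis fusion events from a topology time series
#'
#' Fusion events are counted solely from the changes in the topological
#' indices: a trans fusion (two lobules fusing) decreases the lobule count
#' by one (dN = -1), a cis fusion (a lobule fusing with itself to create a
#' passage) increases the total genus by one (dg = +1). Per frame,
#' dPhi = max(0, N[t-1] - N[t]) and dPsi = max(0, g[t] - g[t-1]); a drop of
#' N by k counts k trans fusions. Increases in N (de novo lumens) and
#' decreases in g (passage closure) are not fusions; they are reported via
#' the `n_increase` / `g_decrease` columns and a message.
#'
#' @param states data.frame of time-ordered organoid states with columns
#'   `N` and `g_total` (e.g. rows from [aggregate_lobules()]).
#' @return `states` with added columns `Phi` and `Psi` (cumulative counts,
#'   starting at 0) plus `n_increase` and `g_decrease` event logs.
#' @examples
#' s <- data.frame(N = c(5, 4, 4, 3), g_total = c(0, 0, 1, 1))
#' count_fusions(s)[, c("Phi", "Psi")]
#' @export
count_fusions <- function(states) {
  stopifnot(nrow(states) >= 2, all(c("N", "g_total") %in% names(states)))
  dN <- diff(states$N)
  dg <- diff(states$g_total)
  dphi <- pmax(0, -dN)
  dpsi <- pmax(0, dg)
  n_inc <- pmax(0, dN)
  g_dec <- pmax(0, -dg)
  if (any(n_inc > 0) || any(g_dec > 0))
    message("count_fusions: ", sum(n_inc), " lobule appearance(s) and ",
            sum(g_dec), " passage closure(s) logged as non-fusion events")
  states$Phi <- c(0L, cumsum(dphi))
  states$Psi <- c(0L, cumsum(dpsi))
  states$n_increase <- c(0L, cumsum(n_inc))
  states$g_decrease <- c(0L, cumsum(g_dec))
  states
}

#' Lobule count normalized to the first frame
#'
#' @param states data.frame with column `N`; `N[1]` must be positive.
#' @return numeric vector `N / N[1]`.
#' @export
normalized_lobule_count <- function(states) {
  if (states$N[1] <= 0) stop("initial lobule count must be positive")
  states$N / states$N[1]
}

#' Track the largest lobule across frames
#'
#' Per frame, selects the lobule with the largest volume and returns its
#' shape/topology row; frames with no lobule are marked as gaps (NA rows).
#'
#' @param frames list of per-lobule metrics data.frames (one per frame).
#' @param times optional frame times (hours).
#' @return data.frame with one row per frame (`time_h`, largest lobule's
#'   metrics, `gap` flag).
#' @export
largest_lobule_track <- function(frames, times = NULL) {
  if (is.null(times)) times <- seq_along(frames)
  rows <- lapply(seq_along(frames), function(i) {
    lt <- frames[[i]]
    if (is.null(lt) || nrow(lt) == 0) {
      data.frame(time_h = times[i], V = NA_real_, A = NA_real_, M = NA_real_,
                 chi = NA_integer_, g = NA_integer_, v = NA_real_,
                 m = NA_real_, gap = TRUE)
    } else {
      j <- which.max(lt$V)
      cbind(data.frame(time_h = times[i]),
            lt[j, c("V", "A", "M", "chi", "g", "v", "m"), drop = FALSE],
            data.frame(gap = FALSE))
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
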