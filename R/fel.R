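#' Boltzmann constant in kcal/(mol K)
#' @export
kB_KCAL <- 0.0019872041

#' Joint probability of two reaction coordinates
#'
#' Normalized 2D histogram of per-frame reaction-coordinate values
#' (e.g. RMSD vs Rg, or PC1 vs PC2).
#'
#' @param r1,r2 numeric per-frame series (equal length, finite).
#' @param bins bins per axis (single number or length 2; >= 2).
#' @param padding fractional range padding per side (default 0.02).
#' @return list: \code{P} (bins1 x bins2, sums to 1), \code{edges1},
#'   \code{edges2}, \code{mid1}, \code{mid2}, \code{bin1}, \code{bin2}
#'   (per-frame bin indices).
#' @export
joint_density <- function(r1, r2, bins = 100, padding = 0.02) {
  stopifnot(length(r1) == length(r2), length(r1) >= 1)
  if (!all(is.finite(r1)) || !all(is.finite(r2)))
    stop("reaction coordinates must be finite")
  bins <- rep_len(as.integer(bins), 2)
  if (any(bins < 2)) stop("need at least 2 bins per axis")
  edges <- function(x, nb) {
    rng <- range(x)
    if (diff(rng) == 0)
      stop("constant reaction coordinate: choose a different coordinate ",
           "or add variation; a single-bin axis carries no landscape")
    pad <- padding * diff(rng)
    seq(rng[1] - pad, rng[2] + pad, length.out = nb + 1)
  }
  e1 <- edges(r1, bins[1]); e2 <- edges(r2, bins[2])
  b1 <- findInterval(r1, e1, rightmost.closed = TRUE, all.inside = TRUE)
  b2 <- findInterval(r2, e2, rightmost.closed = TRUE, all.inside = TRUE)
  P <- matrix(0, bins[1], bins[2])
  for (k in seq_along(b1)) P[b1[k], b2[k]] <- P[b1[k], b2[k]] + 1
  P <- P / length(r1)
  list(P = P, edges1 = e1, edges2 = e2,
       mid1 = (e1[-1] + e1[-length(e1)]) / 2,
       mid2 = (e2[-1] + e2[-length(e2)]) / 2,
       bin1 = b1, bin2 = b2)
}

#' Free energy from a probability grid
#'
#' dG(R1,R2) = -kB T ln( P(R1,R2) / Pmax ), so the most populated bin sits
#' at exactly 0 and empty bins carry +Inf.
#'
#' @param P probability grid (sums to 1).
#' @param temperature temperature in K (> 0).
#' @return dG grid in kcal/mol, same dimensions as P.
#' @export
free_energy <- function(P, temperature = 310) {
  if (temperature <= 0) stop("temperature must be positive")
  pmax_ <- max(P)
  if (pmax_ <= 0) stop("all-zero probability grid")
  dG <- -kB_KCAL * temperature * log(P / pmax_)
  dG[P == 0] <- Inf
  dG
}

#' Free-energy landscape over two reaction coordinates
#'
#' @param r1,r2 per-frame reaction-coordinate series.
#' @param names_rc length-2 character, coordinate names (e.g.
#'   \code{c("RMSD", "Rg")}).
#' @param bins,padding passed to \code{\link{joint_density}}.
#' @param temperature temperature in K.
#' @return object of class \code{"fel"}: the \code{joint_density} fields
#'   plus \code{dG}, \code{temperature}, \code{names_rc}, \code{pmax_at}
#'   (R1,R2 midpoints of the most populated bin), and the raw series
#'   \code{r1}, \code{r2} (kept for well populations).
#' @export
free_energy_landscape <- function(r1, r2, names_rc = c("R1", "R2"),
                                  bins = 100, padding = 0.02,
                                  temperature = 310) {
  jd <- joint_density(r1, r2, bins, padding)
  dG <- free_energy(jd$P, temperature)
  imax <- which(jd$P == max(jd$P), arr.ind = TRUE)[1, ]
  structure(c(jd, list(dG = dG, temperature = temperature,
                       names_rc = names_rc,
                       pmax_at = c(jd$mid1[imax[1]], jd$mid2[imax[2]]),
                       r1 = r1, r2 = r2)),
            class = "fel")
}

#' @export
print.fel <- function(x, ...) {
  cat(sprintf("free-energy landscape %s x %s: %d x %d bins, T = %g K\n",
              x$names_rc[1], x$names_rc[2], length(x$mid1), length(x$mid2),
              x$temperature))
  cat(sprintf("  Pmax bin at (%.3g, %.3g); occupied bins: %d\n",
              x$pmax_at[1], x$pmax_at[2], sum(x$P > 0)))
  invisible(x)
}

#' Population and depth of a declared well
#'
#' A well is a user-declared rectangle in reaction-coordinate space
#' (mirroring the manual square-around-the-minimum procedure); its
#' population is the fraction of frames whose (R1, R2) fall inside, and its
#' depth is the minimum dG over bins intersecting the rectangle.
#'
#' @param fel a \code{\link{free_energy_landscape}}.
#' @param r1_interval,r2_interval length-2 numeric intervals.
#' @return list: \code{population}, \code{min_dG}, \code{rectangle}.
#' @export
well_population <- function(fel, r1_interval, r2_interval) {
  inside <- fel$r1 >= r1_interval[1] & fel$r1 <= r1_interval[2] &
    fel$r2 >= r2_interval[1] & fel$r2 <= r2_interval[2]
  sel1 <- fel$mid1 >= r1_interval[1] & fel$mid1 <= r1_interval[2]
  sel2 <- fel$mid2 >= r2_interval[1] & fel$mid2 <= r2_interval[2]
  min_dG <- if (any(sel1) && any(sel2))
    min(fel$dG[sel1, sel2, drop = FALSE]) else Inf
  list(population = mean(inside), min_dG = min_dG,
       rectangle = list(r1 = r1_interval, r2 = r2_interval))
}

#' Automatic well detection by local-minimum flood fill
#'
#' Convenience extension (not part of the manual published procedure):
#' finds local minima of the dG grid deeper than \code{depth} below the
#' surrounding barrier and grows each into a basin of bins reachable
#' without exceeding \code{min dG + depth}; returns a bounding rectangle
#' per basin, usable with \code{\link{well_population}}.
#'
#' @param fel a \code{fel}.
#' @param depth basin depth in kcal/mol (default 1).
#' @param min_population discard basins holding less than this fraction.
#' @return data.frame (r1_lo, r1_hi, r2_lo, r2_hi, min_dG, population).
#' @export
find_wells <- function(fel, depth = 1, min_population = 0.01) {
  dG <- fel$dG
  nb1 <- nrow(dG); nb2 <- ncol(dG)
  occupied <- is.finite(dG)
  visited <- matrix(FALSE, nb1, nb2)
  wells <- list()
  ord <- order(dG)
  for (lin in ord) {
    if (!occupied[lin] || visited[lin]) next
    i0 <- (lin - 1) %% nb1 + 1; j0 <- (lin - 1) %/% nb1 + 1
    lim <- dG[i0, j0] + depth
    # flood fill of bins below the basin's spill level
    stack <- list(c(i0, j0)); basin <- matrix(FALSE, nb1, nb2)
    while (length(stack)) {
      ij <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      i <- ij[1]; j <- ij[2]
      if (i < 1 || i > nb1 || j < 1 || j > nb2) next
      if (basin[i, j] || !occupied[i, j] || visited[i, j]) next
      if (dG[i, j] > lim) next
      basin[i, j] <- TRUE
      stack <- c(stack, list(c(i - 1, j), c(i + 1, j),
                             c(i, j - 1), c(i, j + 1)))
    }
    visited[basin] <- TRUE
    ii <- which(rowSums(basin) > 0); jj <- which(colSums(basin) > 0)
    w <- list(r1_lo = fel$edges1[min(ii)], r1_hi = fel$edges1[max(ii) + 1],
              r2_lo = fel$edges2[min(jj)], r2_hi = fel$edges2[max(jj) + 1],
              min_dG = dG[i0, j0])
    w$population <- well_population(fel, c(w$r1_lo, w$r1_hi),
                                    c(w$r2_lo, w$r2_hi))$population
    wells[[length(wells) + 1L]] <- w
  }
  df <- do.call(rbind, lapply(wells, as.data.frame))
  df <- df[df$population >= min_population, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Per-domain free-energy landscapes (RMSD vs Rg)
#'
#' Each domain is treated as a dependent part of the whole protein: frames
#' are fitted once to the initial conformation on the global fit selection,
#' then the domain's Calpha RMSD (to frame 1) and Rg are used as reaction
#' coordinates.
#'
#' @param traj a \code{\link{trajectory}}.
#' @param top a \code{\link{topology}}.
#' @param domains a \code{\link{domain_map}}.
#' @param fit global fit selection (e.g. \code{\link{tk_fit_selection}}).
#' @param which_domains domain names (default: all in the map).
#' @param bins,temperature passed to \code{\link{free_energy_landscape}}.
#' @return named list of \code{fel} objects (domains that fail to resolve
#'   are skipped with a warning).
#' @export
per_domain_fel <- function(traj, top, domains, fit, which_domains = NULL,
                           bins = 100, temperature = 310) {
  nms <- which_domains %||% names(domains$domains)
  fitted <- fit_trajectory(traj, fit = fit, top = top)
  ref <- get_frame(fitted, 1)
  out <- list()
  for (nm in nms) {
    res <- range_residues(domains$domains[[nm]])
    idx <- tryCatch(resolve_selection(ca_selection(res), top),
                    error = function(e) NULL)
    if (is.null(idx)) { warning("domain ", nm, " unresolved; skipped"); next }
    all_idx <- resolve_selection(selection(residues = res), top)
    nf <- n_frames(fitted)
    r1 <- vapply(seq_len(nf), function(f)
      plain_rmsd(fitted$coords[f, idx, , drop = TRUE],
                 ref[idx, , drop = FALSE]), numeric(1))
    r2 <- vapply(seq_len(nf), function(f)
      radius_of_gyration(get_frame(fitted, f), top, all_idx), numeric(1))
    out[[nm]] <- tryCatch(
      free_energy_landscape(r1, r2, c("RMSD", "Rg"), bins = bins,
                            temperature = temperature),
      error = function(e) { warning("domain ", nm, ": ", conditionMessage(e))
        NULL })
  }
  out[!vapply(out, is.null, TRUE)]
}

#' Write a landscape grid and optional well report as TSV
#'
#' @param fel a \code{fel}.
#' @param path grid TSV (R1_bin_center, R2_bin_center, P, dG).
#' @param wells optional data.frame from \code{\link{find_wells}}; written
#'   to \code{paste0(path, ".wells.tsv")}.
#' @export
write_fel <- function(fel, path, wells = NULL) {
  grid <- expand.grid(i = seq_along(fel$mid1), j = seq_along(fel$mid2))
  df <- data.frame(R1 = fel$mid1[grid$i], R2 = fel$mid2[grid$j],
                   P = fel$P[cbind(grid$i, grid$j)],
                   dG = fel$dG[cbind(grid$i, grid$j)])
  df$dG[!is.finite(df$dG)] <- NA
  write_tsv_table(df, path,
                  sprintf("FEL %s x %s, T=%gK", fel$names_rc[1],
                          fel$names_rc[2], fel$temperature))
  if (!is.null(wells)) write_tsv_table(wells, paste0(path, ".wells.tsv"),
                                       "well report")
  invisible(path)
}
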