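#' Ensemble-based conformational clustering
#'
#' The reference-picking algorithm for extracting representative
#' conformations from a trajectory: (i) a reference frame is drawn at
#' random from the remaining ensemble and every conformation within the
#' RMSD cutoff r of it is removed; this repeats until the ensemble is
#' exhausted, yielding references pairwise more than r apart; (ii) every
#' frame is assigned to its nearest reference (ties to the lowest reference
#' index).  RMSDs are Calpha RMSDs over the analysis selection.  In
#' \code{mode = "context"} the trajectory is first fitted once to the
#' reference frame on \code{fit} (e.g. the initial TK-domain conformation),
#' so fragment RMSDs retain the fragment's position in the whole protein;
#' in \code{mode = "intrinsic"} each frame is fitted on the selection
#' itself, removing rigid-body motion of the fragment.
#'
#' @param traj a \code{\link{trajectory}}.
#' @param top a \code{\link{topology}}.
#' @param sel analysis selection (e.g. fragment Calpha).
#' @param cutoff RMSD cutoff r in Angstrom (> 0).
#' @param seed integer RNG seed; the reference draw is otherwise
#'   unreproducible.
#' @param mode "context" or "intrinsic" (see above).
#' @param fit fit selection for context mode (default: \code{sel}).
#' @param stride sample every stride-th frame.
#' @return object of class \code{"cluster_set"}: \code{cutoff},
#'   \code{references} (frame indices), \code{assignment} (per sampled
#'   frame), \code{populations} (fractions, sum 1), \code{medoids},
#'   \code{frames} (sampled frame indices), \code{seed}.
#' @export
ensemble_cluster <- function(traj, top, sel, cutoff, seed = 1L,
                             mode = c("context", "intrinsic"), fit = NULL,
                             stride = 1L) {
  mode <- match.arg(mode)
  if (cutoff <= 0) stop("cutoff must be positive")
  frames <- seq(1L, n_frames(traj), by = as.integer(stride))
  idx <- resolve_selection(sel, top)
  ref_frame <- get_frame(traj, 1)
  X <- matrix(NA_real_, length(frames), 3 * length(idx))
  for (k in seq_along(frames)) {
    fr <- get_frame(traj, frames[k])
    fr <- if (mode == "context")
      superpose(fr, ref_frame, fit %||% idx, top)$coords
    else
      superpose(fr, ref_frame, idx, top)$coords
    X[k, ] <- as.vector(t(fr[idx, , drop = FALSE]))
  }
  nat <- length(idx)
  rms_to <- function(v) sqrt(rowSums(sweep(X, 2, v)^2) / nat)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  remaining <- seq_len(nrow(X))
  refs <- integer(0)
  while (length(remaining) > 0L) {
    pick <- remaining[sample.int(length(remaining), 1L)]
    refs <- c(refs, pick)
    d <- sqrt(rowSums(sweep(X[remaining, , drop = FALSE], 2, X[pick, ])^2) / nat)
    remaining <- remaining[d > cutoff]
  }
  D <- matrix(NA_real_, nrow(X), length(refs))
  for (r in seq_along(refs)) D[, r] <- rms_to(X[refs[r], ])
  assignment <- max.col(-D, ties.method = "first")
  pops <- tabulate(assignment, nbins = length(refs)) / nrow(X)
  medoids <- integer(length(refs))
  for (c in seq_along(refs)) {
    members <- which(assignment == c)
    if (length(members) == 1L) { medoids[c] <- members; next }
    Xi <- X[members, , drop = FALSE]
    # medoid: member minimizing mean RMSD to the other members
    g <- rowSums(Xi^2)
    cost <- vapply(seq_along(members), function(m)
      mean(sqrt(pmax(0, g + g[m] - 2 * as.vector(Xi %*% Xi[m, ])) / nat)),
      numeric(1))
    medoids[c] <- members[which.min(cost)]
  }
  structure(list(cutoff = cutoff, references = frames[refs],
                 assignment = assignment, populations = pops,
                 medoids = frames[medoids], frames = frames,
                 seed = as.integer(seed), mode = mode),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("ensemble clustering: cutoff %.2f A, %d cluster(s)\n",
              x$cutoff, length(x$references)))
  ord <- order(x$populations, decreasing = TRUE)
  for (c in ord)
    cat(sprintf("  cluster %d: %.1f%% (medoid frame %d)\n",
                c, 100 * x$populations[c], x$medoids[c]))
  invisible(x)
}

#' Sweep the clustering cutoff
#'
#' Runs \code{\link{ensemble_cluster}} for each cutoff (default
#' 2.0--5.0 Angstrom in 0.5 steps) and summarizes cluster counts and the
#' cumulative population of all clusters holding at least 1% of frames --
#' the selection aid for choosing the cutoff whose major clusters cover
#' more than 95% of the ensemble.
#'
#' @inheritParams ensemble_cluster
#' @param cutoffs numeric vector of cutoffs in Angstrom.
#' @return list: \code{summary} data.frame (cutoff, n_clusters,
#'   n_major, cumulative_major_pct), \code{sets} (per-cutoff cluster_set).
#' @export
cutoff_sweep <- function(traj, top, sel, cutoffs = seq(2, 5, by = 0.5),
                         seed = 1L, mode = "context", fit = NULL,
                         stride = 1L) {
  if (length(cutoffs) == 0L) stop("empty cutoff list")
  sets <- lapply(cutoffs, function(cc)
    ensemble_cluster(traj, top, sel, cc, seed = seed, mode = mode,
                     fit = fit, stride = stride))
  summ <- data.frame(
    cutoff = cutoffs,
    n_clusters = vapply(sets, function(s) length(s$references), 0L),
    n_major = vapply(sets, function(s) sum(s$populations >= 0.01), 0L),
    cumulative_major_pct = vapply(sets, function(s)
      100 * sum(s$populations[s$populations >= 0.01]), numeric(1)))
  list(summary = summ, sets = sets)
}

#' Write a cluster table as TSV and representatives as multi-model PDB
#'
#' @param cs a \code{cluster_set}.
#' @param path output TSV path.
#' @param traj,top optionally write medoid conformations to
#'   \code{paste0(path, ".representatives.pdb")}.
#' @export
write_cluster_table <- function(cs, path, traj = NULL, top = NULL) {
  df <- data.frame(cluster = seq_along(cs$references),
                   population_pct = round(100 * cs$populations, 4),
                   reference_frame = cs$references,
                   medoid_frame = cs$medoids)
  df <- df[order(-df$population_pct), , drop = FALSE]
  write_tsv_table(df, path,
                  sprintf("ensemble clustering cutoff=%.2fA seed=%d mode=%s",
                          cs$cutoff, cs$seed, cs$mode))
  if (!is.null(traj) && !is.null(top)) {
    reps <- trajectory(traj$coords[cs$medoids, , , drop = FALSE],
                       time_step_ps = traj$time_step_ps)
    write_pdb_system(top, reps, paste0(path, ".representatives.pdb"))
  }
  invisible(path)
}
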