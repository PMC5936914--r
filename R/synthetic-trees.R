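#' Simulation configuration for the synthetic fossil-record generator
#'
#' Bundles the rates and geometry used by [simulate_tree()],
#' [simulate_fossil_record()] and the end-to-end pipeline. Ages are in Ma
#' (millions of years before present), rates in events per lineage-Myr.
#'
#' @param seed integer seed controlling all randomness downstream.
#' @param n_tips number of tips (extinct plus extant) the birth-death tree
#'   is conditioned on.
#' @param birth_rate,death_rate per-lineage speciation and extinction rates
#'   (1/Myr); `birth_rate > 0`, `death_rate >= 0`.
#' @param preservation_rate_q expected fossil occurrences per lineage-Myr
#'   under homogeneous Poisson preservation.
#' @param grid_extent numeric vector `c(lat_min, lat_max, lon_min, lon_max)`
#'   in degrees; all simulated occurrences fall inside it.
#' @param slice_boundaries strictly decreasing ages (Ma) delimiting the
#'   time slices used for occupancy; `length(slice_boundaries) - 1` slices.
#' @param geo_sd standard deviation (degrees) of the per-species Gaussian
#'   geographic kernel.
#' @param dating_sd if `NULL` (default), each occurrence's age interval is
#'   the true age plus/minus half the width of its enclosing time slice
#'   (land-mammal-age style binning); otherwise plus/minus `dating_sd` Myr.
#'
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_tips = 60L, birth_rate = 0.25,
                       death_rate = 0.2, preservation_rate_q = 2,
                       grid_extent = c(25, 50, -125, -95),
                       slice_boundaries = default_slice_boundaries(),
                       geo_sd = 2, dating_sd = NULL) {
  stop_if_not_positive(birth_rate, "birth_rate")
  if (death_rate < 0) stop("death_rate must be >= 0")
  stop_if_not_positive(preservation_rate_q, "preservation_rate_q")
  if (any(diff(slice_boundaries) >= 0)) {
    stop("slice_boundaries must be strictly decreasing in age")
  }
  stopifnot(length(grid_extent) == 4, grid_extent[1] < grid_extent[2],
            grid_extent[3] < grid_extent[4])
  structure(list(seed = as.integer(seed), n_tips = as.integer(n_tips),
                 birth_rate = birth_rate, death_rate = death_rate,
                 preservation_rate_q = preservation_rate_q,
                 grid_extent = grid_extent,
                 slice_boundaries = slice_boundaries,
                 geo_sd = geo_sd, dating_sd = dating_sd),
            class = "sim_config")
}

#' Approximate default time-slice boundaries (Ma)
#'
#' Eighteen contiguous slices spanning the last 40 Myr, emulating
#' subdivisions of the North American land mammal ages. The boundaries are
#' approximate and intended for synthetic data; supply your own table for
#' real analyses.
#'
#' @return numeric vector of 19 strictly decreasing ages in Ma.
#' @export
default_slice_boundaries <- function() {
  c(40, 37.5, 35, 33, 30.5, 28, 25.5, 23, 20.5, 18.5,
    16.5, 14.5, 12.5, 10.5, 8.5, 6.5, 4.5, 2.5, 0)
}

#' Time-slice table from boundary ages
#'
#' @param boundaries strictly decreasing ages in Ma.
#' @return data.frame with columns `slice`, `old_ma`, `young_ma`.
#' @export
slice_table <- function(boundaries = default_slice_boundaries()) {
  if (any(diff(boundaries) >= 0)) stop("boundaries must be strictly decreasing")
  n <- length(boundaries) - 1L
  data.frame(slice = paste0("S", seq_len(n)),
             old_ma = boundaries[-(n + 1L)],
             young_ma = boundaries[-1L])
}

# Forward birth-death simulation for a fixed duration t_max, starting from
# one lineage. Returns counts only; used for calibration checks.
#' Forward birth-death lineage count
#'
#' Simulates a constant-rate birth-death process from a single lineage for
#' `t_max` Myr and returns the number of lineages alive at the end. The
#' expectation is `exp((birth - death) * t_max)`.
#'
#' @param birth_rate,death_rate rates per lineage-Myr.
#' @param t_max duration in Myr.
#' @return integer number of surviving lineages (possibly 0).
#' @export
sim_bd_forward <- function(birth_rate, death_rate, t_max) {
  n <- 1L
  t <- 0
  repeat {
    if (n == 0L) return(0L)
    total <- n * (birth_rate + death_rate)
    t <- t + stats::rexp(1, total)
    if (t > t_max) return(n)
    if (stats::runif(1) < birth_rate / (birth_rate + death_rate)) {
      n <- n + 1L
    } else {
      n <- n - 1L
    }
  }
}

#' Simulate a birth-death tree with extinct tips and known history
#'
#' Forward constant-rate birth-death simulation conditioned on reaching
#' `n_tips` total tips (extinct lineages are retained, so the tree is in
#' general non-ultrametric). The simulation stops at the birth event that
#' creates the `n_tips`-th lineage-with-tip; lineages still alive then are
#' the extant tips (age 0 Ma). Runs that go fully extinct before reaching
#' `n_tips` are retried up to `max_retries` times.
#'
#' @param config a [sim_config()].
#' @param max_retries retry budget before declaring the rate combination
#'   infeasible.
#' @return a list with elements `tree` (an [ape] `phylo` with edge lengths
#'   in Myr, tip labels `sp1..spN`) and `history` (data.frame `species`,
#'   `ts`, `te`, `extant`; ages in Ma, `ts >= te >= 0`).
#' @export
simulate_tree <- function(config, max_retries = 1000L) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_tips < 2L) stop("n_tips must be >= 2")
  set.seed(config$seed)
  for (try in seq_len(max_retries)) {
    res <- sim_bd_tree_once(config$n_tips, config$birth_rate, config$death_rate)
    if (!is.null(res)) return(res)
  }
  stop("birth-death simulation failed to reach n_tips within the retry ",
       "budget; rate combination likely infeasible")
}

# One attempt at a forward birth-death tree conditioned on total tip count.
# Bookkeeping: each active lineage has a parent node and a start time;
# events are drawn jointly over all live lineages.
sim_bd_tree_once <- function(n_tips, birth, death) {
  # lineage records: start time (Myr from root), end time (NA while alive)
  start <- c(0, 0)        # root splits immediately into two lineages
  end <- c(NA_real_, NA_real_)
  parent <- c(0L, 0L)     # 0 = root
  child <- list(integer(0), integer(0))
  alive <- c(TRUE, TRUE)
  t <- 0
  n_term <- 0L            # tips finalized (extinct) so far
  repeat {
    n_alive <- sum(alive)
    if (n_alive == 0L) return(NULL)
    if (n_alive + n_term >= n_tips) break
    t <- t + stats::rexp(1, n_alive * (birth + death))
    i <- which(alive)[sample.int(n_alive, 1L)]
    if (stats::runif(1) < birth / (birth + death)) {
      # lineage i splits: close it as an internal node, open two children
      end[i] <- t
      alive[i] <- FALSE
      k <- length(start)
      start <- c(start, t, t); end <- c(end, NA, NA)
      parent <- c(parent, i, i); alive <- c(alive, TRUE, TRUE)
      child[[i]] <- c(k + 1L, k + 2L)
      child[[k + 1L]] <- integer(0); child[[k + 2L]] <- integer(0)
    } else {
      end[i] <- t
      alive[i] <- FALSE
      n_term <- n_term + 1L
    }
  }
  # Stop the clock strictly between the last event and the next one, so
  # the final two sister tips get positive terminal branches (no
  # exchangeable-duplicate tips, which would make trait covariances
  # singular). The state is constant on that interval.
  present <- t + stats::rexp(1, n_alive * (birth + death))
  end[alive] <- present
  is_tip <- lengths(child) == 0L
  extant <- alive & is_tip
  if (sum(is_tip) != n_tips) return(NULL)  # defensive; should not happen
  build_phylo_from_records(start, end, parent, child, is_tip, extant, present)
}

#' Emulate a posterior sample of time-calibrated trees
#'
#' Produces `n` trees sharing the topology of `tree` with edge lengths
#' jittered multiplicatively (lognormal, sd `jitter_sd` on the log
#' scale), emulating the dating uncertainty of a Bayesian tip-dating
#' posterior. The first tree of the sample is the unjittered input.
#'
#' @param tree a `phylo`.
#' @param n number of trees.
#' @param jitter_sd lognormal sd of the edge-length perturbation.
#' @param seed integer seed.
#' @return a `multiPhylo` of length `n`.
#' @export
simulate_posterior_trees <- function(tree, n, jitter_sd = 0.1, seed = 1L) {
  set.seed(child_seed(seed, "posterior_trees"))
  out <- vector("list", n)
  out[[1L]] <- tree
  for (i in seq_len(n)[-1L]) {
    tr <- tree
    tr$edge.length <- tr$edge.length *
      exp(stats::rnorm(length(tr$edge.length), 0, jitter_sd))
    out[[i]] <- tr
  }
  class(out) <- "multiPhylo"
  out
}

# Convert lineage records into an ape phylo plus a TS/TE history table.
build_phylo_from_records <- function(start, end, parent, child, is_tip,
                                     extant, present) {
  n_tip <- sum(is_tip)
  tip_ids <- which(is_tip)
  node_ids <- which(!is_tip)            # internal lineages (they split)
  # ape numbering: tips 1..n, root n+1, internals follow
  lab <- integer(length(start))
  lab[tip_ids] <- seq_len(n_tip)
  root_num <- n_tip + 1L
  lab[node_ids] <- n_tip + 1L + seq_along(node_ids)
  edge <- matrix(0L, nrow = length(start), ncol = 2)
  elen <- numeric(length(start))
  for (i in seq_along(start)) {
    p <- parent[i]
    edge[i, ] <- c(if (p == 0L) root_num else lab[p], lab[i])
    elen[i] <- end[i] - start[i]
  }
  tree <- structure(list(edge = edge, edge.length = elen,
                         tip.label = paste0("sp", seq_len(n_tip)),
                         Nnode = length(node_ids) + 1L),
                    class = "phylo", order = "cladewise")
  tree <- ape::reorder.phylo(tree, "cladewise")
  history <- data.frame(
    species = paste0("sp", lab[tip_ids]),
    ts = present - start[tip_ids],     # origination age, Ma
    te = present - end[tip_ids],       # extinction age, Ma (0 if extant)
    extant = extant[tip_ids])
  history <- history[order(as.integer(sub("sp", "", history$species))), ]
  rownames(history) <- NULL
  history$te[history$extant] <- 0
  list(tree = tree, history = history, present = present)
}
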