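#' Simulate a fossil occurrence record from a true history
#'
#' For each species, occurrence ages are a homogeneous Poisson process
#' with rate `preservation_rate_q` on `[TE, TS]` (so the expected count
#' is `q * duration` and species with zero draws are omitted, emulating
#' unsampled taxa). Each species gets a 2-D Gaussian geographic kernel
#' with a uniformly drawn centre inside `grid_extent`; occurrence
#' coordinates are drawn from the kernel and re-drawn until inside the
#' extent. Localities are formed by snapping coordinates to a 0.1-degree
#' raster, so nearby occurrences share a locality. Age intervals are the
#' true age plus/minus half of the enclosing time slice width
#' (`dating_sd` overrides this with a fixed half-width), clipped at 0.
#'
#' @param history data.frame `species`, `ts`, `te`, `extant` as returned
#'   by [simulate_tree()].
#' @param config a [sim_config()].
#' @param subfamily optional named vector mapping species to subfamily
#'   labels (copied into the output).
#' @return occurrence data.frame: `species`, `subfamily`, `locality_id`,
#'   `lat`, `lon`, `max_age`, `min_age`, `extant`.
#' @export
simulate_fossil_record <- function(history, config, subfamily = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!nrow(history)) stop("empty history")
  set.seed(child_seed(config$seed, "fossil_record"))
  q <- config$preservation_rate_q
  ext <- config$grid_extent
  slices <- slice_table(config$slice_boundaries)
  rows <- lapply(seq_len(nrow(history)), function(i) {
    dur <- history$ts[i] - history$te[i]
    n <- stats::rpois(1, q * dur)
    if (n == 0L) return(NULL)
    ages <- stats::runif(n, history$te[i], history$ts[i])
    ctr <- c(stats::runif(1, ext[1], ext[2]), stats::runif(1, ext[3], ext[4]))
    lat <- numeric(n); lon <- numeric(n)
    for (j in seq_len(n)) {
      repeat {
        la <- stats::rnorm(1, ctr[1], config$geo_sd)
        lo <- stats::rnorm(1, ctr[2], config$geo_sd)
        if (la >= ext[1] && la <= ext[2] && lo >= ext[3] && lo <= ext[4]) {
          lat[j] <- la; lon[j] <- lo
          break
        }
      }
    }
    half <- if (!is.null(config$dating_sd)) rep(config$dating_sd, n) else {
      sl <- assign_slice(ages, slices)
      w <- slices$old_ma[match(sl, slices$slice)] -
        slices$young_ma[match(sl, slices$slice)]
      w[is.na(w)] <- stats::median(slices$old_ma - slices$young_ma)
      w / 2
    }
    data.frame(species = history$species[i],
               subfamily = if (is.null(subfamily)) "clade1"
                           else unname(subfamily[history$species[i]]),
               locality_id = paste0("L", round(lat / 0.1), "_",
                                    round(lon / 0.1)),
               lat = lat, lon = lon,
               max_age = ages + half,
               min_age = pmax(0, ages - half),
               extant = history$extant[i])
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(species = character(0), subfamily = character(0),
                      locality_id = character(0), lat = numeric(0),
                      lon = numeric(0), max_age = numeric(0),
                      min_age = numeric(0), extant = logical(0))
  }
  rownames(out) <- NULL
  out
}

#' Default diet-category centroids for the extant morphoset
#'
#' Centroids of (RBL, RUGA, JD_DL) per diet category. The hyaenid-like
#' (bone-cracking hypercarnivore) centroid has the highest RBL and JD_DL
#' and the lowest RUGA; the hypocarnivore centroid the reverse.
#'
#' @return a named list of 3-vectors.
#' @export
default_diet_centroids <- function() {
  list(hypocarnivore = c(RBL = 0.52, RUGA = 1.35, JD_DL = 0.13),
       mesocarnivore = c(RBL = 0.64, RUGA = 0.95, JD_DL = 0.16),
       hypercarnivore = c(RBL = 0.76, RUGA = 0.60, JD_DL = 0.19),
       hyaenid_like = c(RBL = 0.90, RUGA = 0.35, JD_DL = 0.24))
}

#' Simulate an extant comparative morphometric set
#'
#' Species dietary ratios are their category centroid plus independent
#' Gaussian noise, emulating an extant training set of known diet for the
#' carnivory-index PCA.
#'
#' @param n_per_category named integer vector (categories absent or 0 are
#'   skipped).
#' @param category_means named list of (RBL, RUGA, JD_DL) centroids.
#' @param noise_sd standard deviation of the additive noise (applied on
#'   each ratio, scaled by the spread of centroids for that ratio).
#' @param seed integer seed.
#' @return data.frame `species`, `diet_category`, `RBL`, `RUGA`, `JD_DL`.
#' @export
simulate_extant_morphoset <- function(n_per_category = c(hypocarnivore = 12,
                                                         mesocarnivore = 18,
                                                         hypercarnivore = 12,
                                                         hyaenid_like = 3),
                                      category_means =
                                        default_diet_centroids(),
                                      noise_sd = 0.05, seed = 1L) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  set.seed(child_seed(seed, "extant_morphoset"))
  cats <- names(n_per_category)[n_per_category > 0]
  rows <- lapply(cats, function(cat) {
    n <- n_per_category[[cat]]
    ctr <- category_means[[cat]]
    if (is.null(ctr)) stop("no centroid for category ", cat)
    sds <- noise_sd * c(RBL = 0.4, RUGA = 1.0, JD_DL = 0.12)
    data.frame(species = paste0(substr(cat, 1, 4), "_", seq_len(n)),
               diet_category = cat,
               RBL = ctr["RBL"] + stats::rnorm(n, 0, sds["RBL"]),
               RUGA = pmax(0.05, ctr["RUGA"] + stats::rnorm(n, 0,
                                                            sds["RUGA"])),
               JD_DL = pmax(0.02, ctr["JD_DL"] +
                              stats::rnorm(n, 0, sds["JD_DL"])))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate fossil morphometric measurements from latent traits
#'
#' Maps each species' latent carnivory value (standard-normal scale) and
#' log10 body mass onto the six measured characters: m1 length is
#' back-calculated from mass through the allometric regression, the
#' trigonid blade and grinding-area characters interpolate between the
#' hypo- and hyper-carnivore ratio centroids as carnivory increases, and
#' measurement noise is added. A configurable fraction of dentaries is
#' set missing so the imputation path is exercised.
#'
#' @param carnivory named latent carnivory vector (higher = more
#'   carnivorous).
#' @param log10_mass named log10 body-mass vector (kg).
#' @param subfamily named subfamily vector.
#' @param mass_coeffs allometric coefficients as in
#'   [estimate_body_mass()].
#' @param missing_dentary_frac fraction of species with missing dentary
#'   length.
#' @param noise_sd relative measurement noise.
#' @param seed integer seed.
#' @return morphometric data.frame suitable for
#'   [compute_dietary_ratios()].
#' @export
simulate_fossil_morphoset <- function(carnivory, log10_mass, subfamily,
                                      mass_coeffs = list(a = -2.58,
                                                         b = 2.97),
                                      missing_dentary_frac = 0.3,
                                      noise_sd = 0.02, seed = 1L) {
  set.seed(child_seed(seed, "fossil_morphoset"))
  sp <- names(carnivory)
  n <- length(sp)
  z <- stats::pnorm(scale(carnivory)[, 1])   # carnivory rank in (0, 1)
  lo <- default_diet_centroids()$hypocarnivore
  hi <- default_diet_centroids()$hyaenid_like
  rbl <- lo["RBL"] + z * (hi["RBL"] - lo["RBL"])
  ruga <- lo["RUGA"] + z * (hi["RUGA"] - lo["RUGA"])
  jddl <- lo["JD_DL"] + z * (hi["JD_DL"] - lo["JD_DL"])
  m1 <- 10^((log10_mass[sp] - mass_coeffs$a) / mass_coeffs$b)
  noisy <- function(x) x * exp(stats::rnorm(n, 0, noise_sd))
  m1 <- noisy(m1)
  blade <- pmin(noisy(rbl * m1), m1)
  p4 <- noisy(0.9 * m1)
  uga <- noisy((ruga * p4)^2)
  dl <- noisy(6 * m1 * ifelse(subfamily[sp] == unique(subfamily)[1],
                              1, 0.85))
  jd <- noisy(jddl * dl)
  dl[stats::runif(n) < missing_dentary_frac] <- NA
  data.frame(species = sp, subfamily = unname(subfamily[sp]),
             m1_length = unname(m1), trigonid_blade_length = unname(blade),
             upper_grinding_area = unname(uga), p4_length = unname(p4),
             jaw_depth = unname(jd), dentary_length = unname(dl))
}
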