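#' Configuration for the end-to-end pipeline
#'
#' With `input_files = NULL` (default) all inputs are generated by the
#' synthetic-data module from the master seed, with known ground truth;
#' otherwise a named list of file paths (`occurrences`, `extant_morpho`,
#' `fossil_morpho`, `trees`, `slices`) is ingested. Every stage seed is
#' derived deterministically from `seed`.
#'
#' Default trait models for the synthetic run: log10 body mass evolves
#' under Drift with a positive directional term (a Cope's-Rule-like size
#' increase), carnivory under Brownian motion; the rates are set so tip
#' spreads match typical carnivoran values (log-mass spread about 0.4,
#' carnivory index spread near 1).
#'
#' @param seed master seed.
#' @param out_dir output directory for tables and the manifest.
#' @param sim a [sim_config()] for the synthetic inputs.
#' @param trait_models named list of [model_spec()] (`log10_mass`,
#'   `carnivory`).
#' @param n_trees posterior trees to generate/use.
#' @param models trait-evolution models to compare.
#' @param tau quantile-regression quantiles.
#' @param n_bootstrap bootstrap replications for quantile fits.
#' @param mcmc list of [estimate_durations()] settings (`iterations`,
#'   `burnin`, `thin`).
#' @param mass_coeffs allometric mass-regression coefficients.
#' @param outliers species excluded from side regressions.
#' @param n_perm permutations for Blomberg's K.
#' @param input_files optional named list of input paths.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, out_dir = tempfile("paleomacro_run_"),
                            sim = sim_config(seed = seed),
                            trait_models = list(
                              log10_mass = model_spec("Drift", z0 = 0.5,
                                                      sigma2 = 0.005,
                                                      mu_drift = 0.02),
                              carnivory = model_spec("BM", z0 = 0,
                                                     sigma2 = 0.02)),
                            n_trees = 50L, models = c("BM", "OU", "ACDC",
                                                      "Trend", "Drift",
                                                      "Div"),
                            tau = c(0.6, 0.7, 0.8, 0.9),
                            n_bootstrap = 1000L,
                            mcmc = list(iterations = 2e5, burnin = 2e4),
                            mass_coeffs = list(a = -2.58, b = 2.97),
                            outliers = character(0), n_perm = 199L,
                            input_files = NULL) {
  structure(list(seed = as.integer(seed), out_dir = out_dir, sim = sim,
                 trait_models = trait_models, n_trees = as.integer(n_trees),
                 models = models, tau = tau, n_bootstrap = n_bootstrap,
                 mcmc = mcmc, mass_coeffs = mass_coeffs,
                 outliers = outliers, n_perm = n_perm,
                 input_files = input_files),
            class = "pipeline_config")
}

# Assign a subfamily label to each tip: the two clades descending from
# the root become "subfamilyA"/"subfamilyB".
root_clade_subfamilies <- function(tree) {
  n <- length(tree$tip.label)
  root <- n + 1L
  kids <- tree$edge[tree$edge[, 1] == root, 2]
  lab <- stats::setNames(rep("subfamilyB", n), tree$tip.label)
  first <- if (kids[1] <= n) tree$tip.label[kids[1]]
           else ape::extract.clade(tree, kids[1])$tip.label
  lab[first] <- "subfamilyA"
  lab
}

#' Run the full macroecology pipeline
#'
#' Executes, in order: synthetic input generation (or file ingest);
#' carnivory-index construction and fossil projection; body-mass
#' estimation; occurrence filtering; duration MCMC; grid occupancy and
#' maximum locality coverage; the merged species table; the
#' signal-summary table (median, median absolute deviation, Pagel's
#' lambda, Blomberg's K per variable); the median-split specialization
#' and quantile-regression analysis; the nested duration models; and
#' trait-evolution model selection over the posterior tree sample for
#' the family and each subfamily with at least 8 species. All tables are
#' written as CSV under `config$out_dir` together with a JSON run
#' manifest. When no trees are available the phylogenetic stages are
#' skipped with a warning and the non-phylogenetic tables are still
#' produced.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) a list with all stage outputs and output paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- proc.time()[3]
  timings <- c()
  stage <- function(name, expr) {
    s <- proc.time()[3]
    res <- tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    timings[[name]] <<- unname(round(proc.time()[3] - s, 2))
    res
  }

  inputs <- stage("inputs", pipeline_inputs(config))
  trees <- inputs$trees

  ecom <- stage("carnivory_index", {
    model <- fit_carnivory_index(inputs$extant_morpho)
    imputer <- fit_dentary_imputer(inputs$fossil_morpho,
                                   pooled_fallback = TRUE)
    ratios <- compute_dietary_ratios(inputs$fossil_morpho, imputer)
    proj <- project_carnivory(model, ratios, recenter = "fit")
    mass <- estimate_body_mass(inputs$fossil_morpho$m1_length,
                               config$mass_coeffs)
    list(model = proj$model, ratios = ratios, scores = proj$scores,
         excluded = proj$excluded,
         mass = data.frame(species = inputs$fossil_morpho$species,
                           log10_mass = mass$log10_mass))
  })

  filt <- stage("filter", filter_species(inputs$occurrences))
  occ_inc <- inputs$occurrences[inputs$occurrences$species %in%
                                  filt$included, ]

  dur <- stage("durations", do.call(estimate_durations, c(
    list(occ = occ_inc, seed = child_seed(config$seed, "mcmc")),
    config$mcmc)))

  occup <- stage("occupancy", {
    ob <- occupancy_by_slice(occ_inc, inputs$slices)
    max_locality_coverage(ob, inputs$slices)
  })

  merged <- stage("merge", {
    m <- Reduce(function(a, b) merge(a, b, by = "species"), list(
      data.frame(species = ecom$scores$species,
                 carnivory = ecom$scores$pc1),
      ecom$mass, dur$durations[, c("species", "duration")],
      stats::setNames(occup[, c("species", "max_loc_cover")],
                      c("species", "max_loc_cover"))))
    m
  })
  dropped <- setdiff(filt$included, merged$species)
  if (length(dropped)) {
    message(length(dropped), " species dropped at merge (missing a stage ",
            "value): ", paste(utils::head(dropped, 8), collapse = ", "))
  }

  table1 <- if (is.null(trees)) {
    warning("no trees available: signal table, PGLS and model-selection ",
            "stages skipped")
    NULL
  } else {
    stage("signal_table", signal_summary_table(
      merged, trees[[1]], n_perm = config$n_perm,
      seed = child_seed(config$seed, "signal")))
  }

  spec_data <- stage("specialization", build_specialization_dataset(
    merged[, c("species", "carnivory")],
    merged[, c("species", "duration", "log10_mass", "max_loc_cover")],
    exclusions = config$outliers))
  sides <- stage("side_regressions", fit_side_regressions(
    spec_data, tree = if (is.null(trees)) NULL else trees[[1]],
    tau = config$tau, n_bootstrap = config$n_bootstrap,
    seed = child_seed(config$seed, "qr")))
  table2 <- do.call(rbind, lapply(names(sides), function(s) {
    cbind(side = s, sides[[s]]$quantile)
  }))

  table3 <- stage("nested_models", nested_duration_models(merged))

  fig5 <- if (is.null(trees)) NULL else stage("model_selection", {
    clades <- list(all = merged$species)
    sf <- inputs$subfamily
    if (!is.null(sf)) {
      for (s in unique(sf)) {
        in_clade <- intersect(names(sf)[sf == s], merged$species)
        if (length(in_clade) >= 8) clades[[s]] <- in_clade
      }
    }
    out <- list()
    for (trait_name in c("log10_mass", "carnivory")) {
      tv <- stats::setNames(merged[[trait_name]], merged$species)
      for (cl in names(clades)) {
        fm <- fit_over_posterior(trees, tv[names(tv) %in% clades[[cl]]],
                                 models = config$models,
                                 n_trees = config$n_trees)
        out[[paste(trait_name, cl, sep = ".")]] <-
          data.frame(trait = trait_name, clade = cl,
                     model = names(fm$median_weight),
                     median_weight = unname(fm$median_weight),
                     n_trees = fm$n_trees)
      }
    }
    do.call(rbind, out)
  })

  paths <- stage("write", {
    w <- function(obj, name) {
      if (is.null(obj)) return(NULL)
      p <- file.path(config$out_dir, name)
      utils::write.csv(obj, p, row.names = FALSE)
      p
    }
    list(
      merged = w(merged, "species_table.csv"),
      durations = w(dur$durations, "durations.csv"),
      occupancy = w(occup, "occupancy.csv"),
      scores = w(ecom$scores, "carnivory_scores.csv"),
      exclusions = w(filt$excluded, "excluded_species.csv"),
      table1 = w(table1, "table1_signal.csv"),
      table2 = w(table2, "table2_quantile.csv"),
      table3 = w(table3, "table3_nested.csv"),
      fig5 = w(fig5, "fig5_model_weights.csv"))
  })

  manifest <- list(
    package = "paleomacro",
    version = as.character(utils::packageVersion("paleomacro")),
    seed = config$seed,
    n_species_input = length(unique(inputs$occurrences$species)),
    n_species_included = length(filt$included),
    n_species_merged = nrow(merged),
    exclusions = as.list(filt$report),
    settings = list(n_trees = config$n_trees, models = config$models,
                    tau = config$tau, n_bootstrap = config$n_bootstrap,
                    mcmc = config$mcmc),
    outputs = lapply(Filter(Negate(is.null), paths), basename),
    md5 = as.list(tools::md5sum(unlist(Filter(Negate(is.null), paths)))),
    timings_s = as.list(timings),
    total_s = round(proc.time()[3] - t0, 2))
  names(manifest$md5) <- basename(names(manifest$md5))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(inputs = inputs, ecomorph = ecom, filter = filt,
                 durations = dur, occupancy = occup, merged = merged,
                 table1 = table1, specialization = spec_data,
                 sides = sides, table2 = table2, table3 = table3,
                 fig5 = fig5, paths = paths, manifest = manifest))
}

# Generate (or read) the pipeline inputs.
pipeline_inputs <- function(config) {
  if (!is.null(config$input_files)) {
    f <- config$input_files
    for (p in unlist(f)) if (!is.null(p) && !file.exists(p)) {
      stop("input file not found: ", p)
    }
    trees <- if (!is.null(f$trees)) read_trees(f$trees) else NULL
    slices <- if (!is.null(f$slices)) utils::read.csv(f$slices)
              else slice_table()
    occ <- utils::read.csv(f$occurrences)
    sf <- NULL
    if ("subfamily" %in% names(occ)) {
      sf <- stats::setNames(occ$subfamily, occ$species)
      sf <- sf[!duplicated(names(sf))]
    }
    return(list(occurrences = occ,
                extant_morpho = utils::read.csv(f$extant_morpho),
                fossil_morpho = utils::read.csv(f$fossil_morpho),
                trees = trees, slices = slices, subfamily = sf,
                history = NULL))
  }
  sim <- config$sim
  tr <- simulate_tree(sim)
  sf <- root_clade_subfamilies(tr$tree)
  trait_seed <- child_seed(config$seed, "traits")
  lm10 <- simulate_trait(tr$tree, config$trait_models$log10_mass,
                         seed = trait_seed)
  carn <- simulate_trait(tr$tree, config$trait_models$carnivory,
                         seed = trait_seed + 1L)
  occ <- simulate_fossil_record(tr$history, sim, subfamily = sf)
  extant <- simulate_extant_morphoset(seed = child_seed(config$seed,
                                                        "extant"))
  fossil <- simulate_fossil_morphoset(carn, lm10, sf,
                                      mass_coeffs = config$mass_coeffs,
                                      seed = child_seed(config$seed,
                                                        "fosmorph"))
  trees <- simulate_posterior_trees(tr$tree, config$n_trees,
                                    seed = child_seed(config$seed,
                                                      "trees"))
  list(occurrences = occ, extant_morpho = extant, fossil_morpho = fossil,
       trees = trees, slices = slice_table(sim$slice_boundaries),
       subfamily = sf,
       history = tr$history,
       true_traits = data.frame(species = names(lm10),
                                log10_mass = unname(lm10),
                                carnivory = unname(carn)))
}

#' Read trees from Newick or NEXUS
#'
#' @param path file path; `.nex`/`.nexus` is read as NEXUS, anything else
#'   as Newick.
#' @return a `multiPhylo`.
#' @export
read_trees <- function(path) {
  tr <- if (grepl("\\.nexus?$", path, ignore.case = TRUE)) {
    ape::read.nexus(path)
  } else {
    ape::read.tree(path)
  }
  if (inherits(tr, "phylo")) tr <- structure(list(tr), class = "multiPhylo")
  tr
}

# Summary + signal statistics table (median, MAD, lambda, K) for the
# merged species table.
signal_summary_table <- function(merged, tree, n_perm = 199L, seed = 1L) {
  vars <- c("log10_mass", "carnivory", "duration", "max_loc_cover")
  shared <- intersect(tree$tip.label, merged$species)
  tr <- ape::keep.tip(tree, shared)
  rows <- lapply(vars, function(v) {
    x <- stats::setNames(merged[[v]], merged$species)[shared]
    sig <- pagel_lambda_ml(tr, x)
    K <- blomberg_k(tr, x, n_perm = n_perm,
                    seed = child_seed(seed, paste0("K_", v)))
    data.frame(metric = v, median = stats::median(merged[[v]]),
               mad = stats::mad(merged[[v]]),
               pagel_lambda = sig$lambda, lambda_p = sig$p,
               blomberg_k = K$K, k_p = K$p)
  })
  do.call(rbind, rows)
}
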