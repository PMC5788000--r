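#' Run the 13-scenario virtual experiment
#'
#' Control (no water stress, no limiting functions) plus the factorial of
#' three deficit-irrigation profiles (LS, MS, SS) by four limitation
#' hypotheses (none, photosynthesis_only, growth_only, both), all on the
#' same tree and weather. Outputs a comparison table of percentage change
#' versus the well-watered control at harvest for carbon assimilation,
#' vegetative dry-mass growth (leafy shoots + water sprouts + new roots),
#' fruit dry and fresh mass, dry matter content, fresh-basis sugar
#' concentration, per-fruit sugar content, and perennial dry-mass growth.
#'
#' @param tree an \code{orchard_tree}.
#' @param seed seed for the synthetic forcing (the weather is shared across
#'   scenarios; only the water-potential boundary differs by profile).
#' @param days season length in days.
#' @param params parameter set.
#' @param forcings optional named list of pre-built forcings (NS, LS, MS,
#'   SS); generated when NULL.
#' @param out optional path for the comparison table CSV.
#' @return list with \code{results} (named list of \code{season_result}),
#'   \code{table} (percentage-change data frame), \code{failures} (named
#'   character vector of error messages for scenarios that failed).
#' @export
run_scenarios <- function(tree, seed = 1, days = 150,
                          params = default_params(), forcings = NULL,
                          out = NULL) {
  profiles <- c("NS", "LS", "MS", "SS")
  if (is.null(forcings)) {
    forcings <- lapply(profiles, function(p)
      generate_synthetic_forcing(seed, days = days, profile = p,
                                 params = params))
    names(forcings) <- profiles
  }
  specs <- list(list(profile = "NS", hypothesis = "none"))
  for (p in c("LS", "MS", "SS"))
    for (h in c("none", "photosynthesis_only", "growth_only", "both"))
      specs[[length(specs) + 1]] <- list(profile = p, hypothesis = h)

  results <- list(); failures <- character(0)
  for (sp in specs) {
    key <- paste(sp$profile, sp$hypothesis, sep = ":")
    res <- tryCatch(
      simulate_season(tree, forcings[[sp$profile]], params, sp$hypothesis),
      error = function(e) e)
    if (inherits(res, "error")) {
      failures[key] <- conditionMessage(res)
    } else {
      results[[key]] <- res
    }
  }
  ctrl <- results[["NS:none"]]
  if (is.null(ctrl)) stop("control scenario failed: ", failures["NS:none"])

  metrics <- c(assim = "assim_gC", veg_dm = "veg_growth_dm",
               fruit_dm = "fruit_dm", fruit_fm = "fruit_fm", dmc = "dmc",
               sugar_conc = "sugar_conc_fm", sugar_content = "sugar_mass",
               perennial_dm = "perennial_growth_dm")
  tab <- do.call(rbind, lapply(names(results), function(key) {
    r <- results[[key]]
    pc <- 100 * (r$totals[metrics] - ctrl$totals[metrics]) /
      abs(ctrl$totals[metrics])
    df <- as.data.frame(as.list(pc))
    names(df) <- names(metrics)
    cbind(data.frame(scenario = key, profile = r$profile,
                     hypothesis = r$hypothesis), df)
  }))
  rownames(tab) <- NULL
  if (!is.null(out)) utils::write.csv(tab, out, row.names = FALSE)
  list(results = results, table = tab, failures = failures)
}

#' Harvest summary of a season
#'
#' Fruit fresh-mass class distribution over configurable bins plus the
#' per-unit composition table.
#'
#' @param result a \code{season_result}.
#' @param class_width fresh-mass class width, g (classes are
#'   \code{[i*w, (i+1)*w)}).
#' @return list with \code{histogram} (data frame: class lower edge, upper
#'   edge, fruit count), \code{mean_fm} (crop-weighted mean fresh mass, g)
#'   and \code{composition} (the per-unit harvest table).
#' @export
harvest_summary <- function(result, class_width = 10) {
  fh <- result$fu_harvest
  fh <- fh[fh$n_fruits > 0, ]
  if (nrow(fh) == 0) stop("no fruit-bearing units at harvest")
  lo <- floor(fh$fruit_fm / class_width) * class_width
  agg <- stats::aggregate(fh$n_fruits, by = list(lower = lo), FUN = sum)
  hist <- data.frame(lower = agg$lower, upper = agg$lower + class_width,
                     count = agg$x)
  hist <- hist[order(hist$lower), ]
  list(histogram = hist,
       mean_fm = sum(fh$fruit_fm * fh$n_fruits) / sum(fh$n_fruits),
       composition = result$fu_harvest)
}
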