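#' Run the analysis pipeline end to end
#'
#' Orchestrates the configured stages over a directory of input tables (or
#' a synthetic dataset generated on the fly), writing per-stage TSV outputs
#' and a JSON manifest recording inputs, thresholds, seed and package
#' version.  Stage randomness is derived from the single config seed via
#' fixed per-stage offsets, so a rerun with the same config reproduces
#' stochastic stages exactly.
#'
#' @param config list with elements:
#'   \describe{
#'     \item{out_dir}{output directory (created if absent).}
#'     \item{seed}{integer master seed.}
#'     \item{stages}{character subset of `c("simulate", "cohort",
#'       "drivers", "clock", "msce_fit", "seg")` (default: all).}
#'     \item{inputs}{optional named list of file paths (`cohort`,
#'       `mutations`, `incidence`, `expression`); stages without inputs
#'       require the `simulate` stage.}
#'     \item{thresholds}{optional overrides: `age_floor` (20),
#'       `recurrence` (4), `chasm` (0.9), `seg` (0.69).}
#'     \item{sim}{optional arguments forwarded to [sim_config()].}
#'     \item{mcmc}{optional list: `n_cycles`, `burn_in`, `free`.}
#'     \item{sojourn_by_sex}{named vector for the clock stage
#'       (default `c(male = 8.35, female = 9.64)`).}
#'   }
#' @return Invisibly, a list of stage results; side effect: files under
#'   `out_dir` plus `manifest.json`.
#' @export
run_pipeline <- function(config) {
  stages_all <- c("simulate", "cohort", "drivers", "clock", "msce_fit",
                  "seg")
  stages <- config$stages %||% stages_all
  unknown <- setdiff(stages, stages_all)
  if (length(unknown))
    stop("unknown stage(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (is.null(config$out_dir)) stop("config$out_dir required", call. = FALSE)
  seed <- config$seed %||% 1L
  thr <- utils::modifyList(list(age_floor = 20, recurrence = 4,
                                chasm = 0.9, seg = 0.69),
                           config$thresholds %||% list())
  inputs <- config$inputs %||% list()

  # pre-flight: every requested stage must have a data source
  needs <- list(cohort = "cohort", drivers = "mutations",
                clock = "mutations", msce_fit = "incidence",
                seg = "expression")
  for (st in intersect(stages, names(needs))) {
    src <- needs[[st]]
    if (is.null(inputs[[src]]) && !"simulate" %in% stages)
      stop("stage '", st, "' needs input '", src,
           "' or the simulate stage", call. = FALSE)
    if (!is.null(inputs[[src]]) && !file.exists(inputs[[src]]))
      stop("input file not found: ", inputs[[src]], call. = FALSE)
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- list()
  outfile <- function(name) file.path(config$out_dir, name)

  if ("simulate" %in% stages) {
    sc <- do.call(sim_config, utils::modifyList(list(seed = seed),
                                                config$sim %||% list()))
    geno <- gen_hla_genotypes(sc)
    cohort <- gen_cohort(sc, geno)
    muts <- gen_mutation_table(sc, cohort)
    write_cohort(cohort, outfile("cohort.tsv"))
    write_mutation_table(muts, outfile("mutations.tsv"))
    res$simulate <- list(cohort = cohort, mutations = muts, config = sc)
  }

  cohort <- if (!is.null(inputs$cohort)) read_cohort(inputs$cohort)
  else res$simulate$cohort
  muts <- if (!is.null(inputs$mutations))
    read_mutation_table(inputs$mutations) else res$simulate$mutations

  if ("cohort" %in% stages) {
    cohort_f <- filter_cohort(cohort)
    if (!"ai_carrier" %in% names(cohort_f)) {
      cs <- carrier_status(cohort_f, ai_allele_set())
      cohort_f$ai_carrier <- cs$carrier
      cohort_f$ai_count <- cs$count
    }
    mw <- mw_age_comparison(cohort_f$age_dx[cohort_f$ai_carrier],
                            cohort_f$age_dx[!cohort_f$ai_carrier])
    ols <- ols_age_model(cohort_f, exposure = "ai_count",
                         covariates = intersect("sex", names(cohort_f)))
    assoc <- data.frame(analysis = c("mw_carrier", "ols_per_allele"),
                        estimate = c(mw$median_diff,
                                     ols$estimate[ols$term == "ai_count"]),
                        p_value = c(mw$p_value,
                                    ols$p_value[ols$term == "ai_count"]))
    utils::write.table(assoc, outfile("cohort_associations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    res$cohort <- list(filtered = cohort_f, mw = mw, ols = ols)
  }

  if ("drivers" %in% stages) {
    ds <- build_driver_set(muts, min_tumors = thr$recurrence,
                           min_chasm = thr$chasm)
    prov <- data.frame(mutation_id = ds$union,
                       subset = rep(c("recurrent", "chasm"),
                                    c(length(ds$recurrent),
                                      length(ds$chasm))))
    utils::write.table(prov, outfile("drivers.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    res$drivers <- ds
  }

  if ("clock" %in% stages) {
    counts <- count_uv_corrected_sbs1(muts, individuals = cohort$id)
    model <- fit_clock_model(cohort, counts)
    sbs <- config$sojourn_by_sex %||% c(male = 8.35, female = 9.64)
    onsets <- personalized_onset(cohort, counts, sbs, model)
    utils::write.table(onsets, outfile("onsets.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    res$clock <- list(counts = counts, model = model, onsets = onsets)
  }

  if ("msce_fit" %in% stages) {
    if (!is.null(inputs$incidence)) {
      inc <- read_incidence(inputs$incidence)
      init <- do.call(tsce_params, config$msce_init %||%
                        list(X = 1e7, nu = 1e-7, alpha = 9, beta = 8.7,
                             mu = 1e-6, tau = 9))
    } else {
      init <- do.call(tsce_params, config$msce_init %||%
                        list(X = 1e7, nu = 1e-7, alpha = 9, beta = 8.7,
                             mu = 1e-6, tau = 9))
      design <- data.frame(age_lo = seq(20, 80, 5),
                           age_hi = seq(25, 85, 5),
                           person_years = 5e6)
      inc <- gen_incidence(init, design, seed = seed + 10L)
    }
    mc <- config$mcmc %||% list()
    fit <- fit_mcmc(inc, init, free = mc$free %||% c("nu", "tau"),
                    n_cycles = mc$n_cycles %||% 20000L,
                    burn_in = mc$burn_in %||% 800L, seed = seed + 11L)
    utils::write.table(fit$summary, outfile("msce_posterior.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    res$msce_fit <- fit
  }

  if ("seg" %in% stages) {
    mat <- if (!is.null(inputs$expression))
      read_expression_matrix(inputs$expression)
    else {
      sc <- res$simulate$config %||% sim_config(seed = seed)
      gen_expression_matrix(sc)
    }
    scores <- seg_scores(expression_prefilter(mat))
    utils::write.table(scores[, c("gene", "score", "lambda", "cv",
                                  "omega")],
                       outfile("seg_scores.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    res$seg <- scores
  }

  manifest <- list(package = "melprotect",
                   version = as.character(utils::packageVersion("melprotect")),
                   seed = seed, stages = stages, thresholds = thr,
                   inputs = inputs,
                   timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, outfile("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
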