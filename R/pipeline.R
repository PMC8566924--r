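# End-to-end orchestration: dataset -> family comparison by repeated CV ->
# refit of the winning family -> VSR sensitivity ranking -> four-optimizer
# maximization, with a writable report.

#' Pipeline configuration
#'
#' @param traits Traits to analyze (default all five).
#' @param families Surrogate families compared (default all three).
#' @param cv_k,cv_repeats,cv_seed Fold plan of the family comparison
#'   (default 5-fold, 10 repeats).
#' @param sigma_grid GRNN width grid for \code{\link{select_sigma}}.
#' @param hidden_candidates MLP hidden-size candidates.
#' @param mf_per_input ANFIS membership functions per input.
#' @param optim An \code{\link{optim_control}} shared by the four
#'   optimizers.
#' @param seed Master seed for model fits.
#' @return A \code{pipeline_config} list.
#' @export
pipeline_config <- function(traits = growth_traits(),
                            families = c("grnn", "mlp", "anfis"),
                            cv_k = 5, cv_repeats = 10, cv_seed = 101,
                            sigma_grid = NULL,
                            hidden_candidates = c(2, 4, 8, 12),
                            mf_per_input = 3,
                            optim = optim_control(),
                            seed = 1) {
  bad <- setdiff(traits, growth_traits())
  if (length(bad) > 0) stop("unknown trait(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(families, c("grnn", "mlp", "anfis"))
  if (length(bad) > 0) stop("unknown family(s): ", paste(bad, collapse = ", "))
  structure(list(traits = traits, families = families, cv_k = cv_k,
                 cv_repeats = cv_repeats, cv_seed = cv_seed,
                 sigma_grid = sigma_grid,
                 hidden_candidates = hidden_candidates,
                 mf_per_input = mf_per_input, optim = optim, seed = seed),
            class = "pipeline_config")
}

#' Run the full modelling-and-optimization pipeline
#'
#' Per trait: (1) selects family hyperparameters (GRNN width by CV grid
#' search, MLP hidden size by CV, ANFIS at the configured membership
#' count); (2) scores every family by repeated k-fold CV (target Box-Cox
#' and input scaling refit inside each training fold); (3) picks the family
#' with the highest mean CV test R-squared (ties broken by lower test
#' RMSE), refits it on all data; (4) ranks input importance by VSR; and
#' (5) maximizes the refitted surrogate with all four optimizers. A trait
#' whose stage fails is recorded and the remaining traits still run.
#'
#' @param dataset A \code{growth_dataset}; default the packaged experiment.
#' @param config A \code{\link{pipeline_config}}.
#' @return A \code{pipeline_report}: list with data frames \code{cv}
#'   (family x trait x partition mean indices), \code{sensitivity}
#'   (trait x input VSR and rank), \code{optimization} (trait x algorithm
#'   best conditions and value), \code{chosen} (winning family per trait),
#'   the fitted \code{models}, full \code{optim_results}, \code{config} and
#'   \code{errors}.
#' @export
run_pipeline <- function(dataset = growth_data(),
                         config = pipeline_config()) {
  dataset <- validate_growth_dataset(as.data.frame(dataset))
  plan <- make_folds(nrow(dataset), k = config$cv_k,
                     repeats = config$cv_repeats, seed = config$cv_seed)
  bounds <- input_bounds()
  cv_rows <- list(); sens_rows <- list(); opt_rows <- list()
  chosen <- list(); models <- list(); optim_results <- list()
  errors <- list()
  for (trait in config$traits) {
    tm <- trait_matrix(dataset, trait)
    step <- "hyperparameters"
    res <- tryCatch({
      hp <- list()
      if ("grnn" %in% config$families) {
        sig <- select_sigma(tm$X, tm$y, plan, grid = config$sigma_grid,
                            bounds = bounds)
        hp$grnn <- list(sigma = as.numeric(sig), bounds = bounds)
      }
      if ("mlp" %in% config$families) {
        hs <- select_hidden_size(tm$X, tm$y, plan,
                                 candidates = config$hidden_candidates,
                                 seed = config$seed, bounds = bounds)
        hp$mlp <- list(hidden_size = as.integer(hs), seed = config$seed,
                       bounds = bounds)
      }
      if ("anfis" %in% config$families) {
        hp$anfis <- list(mf_per_input = config$mf_per_input,
                         seed = config$seed, bounds = bounds)
      }
      step <- "cross-validation"
      fam_summaries <- list()
      for (fam in config$families) {
        rep <- evaluate_cv(fam, tm$X, tm$y, plan, hp[[fam]])
        s <- summary(rep)
        s$trait <- trait
        fam_summaries[[fam]] <- s
      }
      cv_tab <- do.call(rbind, fam_summaries)
      test_tab <- cv_tab[cv_tab$partition == "test", ]
      best <- order(-test_tab$r2, test_tab$rmse)[1]
      fam <- test_tab$family[best]
      step <- "refit"
      model <- family_fitters()[[fam]](tm$X, tm$y,
                                       c(hp[[fam]], list(trait = trait)))
      step <- "sensitivity"
      cv_rmse <- mean(test_tab$rmse[test_tab$family == fam])
      sens <- rank_inputs(model, tm$X, tm$y, rmse_full = cv_rmse)
      sens$trait <- trait
      step <- "optimization"
      opt <- optimize_all(surrogate_problem(model, bounds), config$optim)
      list(cv = cv_tab, fam = fam, model = model, sens = sens, opt = opt)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[[trait]] <- paste0(step, ": ", conditionMessage(res))
      next
    }
    cv_rows[[trait]] <- res$cv
    chosen[[trait]] <- res$fam
    models[[trait]] <- res$model
    sens_rows[[trait]] <- res$sens
    optim_results[[trait]] <- res$opt
    tab <- res$opt$table
    tab$trait <- trait
    names(tab)[match(paste0("x", seq_along(growth_inputs())), names(tab))] <-
      growth_inputs()
    opt_rows[[trait]] <- tab
  }
  bind <- function(lst) if (length(lst)) do.call(rbind, unname(lst)) else NULL
  report <- list(cv = bind(cv_rows), sensitivity = bind(sens_rows),
                 optimization = bind(opt_rows),
                 chosen = unlist(chosen), models = models,
                 optim_results = optim_results, config = config,
                 errors = errors,
                 seeds = c(cv = config$cv_seed, fit = config$seed,
                           optim = config$optim$seed))
  class(report) <- "pipeline_report"
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Growth modelling & optimization report\n")
  cat("  traits:", paste(names(x$chosen), collapse = ", "), "\n")
  cat("  chosen families:", paste(x$chosen, collapse = ", "), "\n")
  if (!is.null(x$optimization)) {
    cat("  optimization entries:", nrow(x$optimization), "\n")
  }
  if (length(x$errors) > 0) {
    cat("  failed stages:\n")
    for (tr in names(x$errors)) cat("   ", tr, "-", x$errors[[tr]], "\n")
  }
  invisible(x)
}

#' Write / load a pipeline report
#'
#' Writes the three report tables as CSV (model comparison, sensitivity,
#' optimization), plus a JSON summary with the chosen families, seeds and
#' configuration needed for a bit-exact re-run. Files are written to a
#' temporary name and renamed into place so a failed write never leaves a
#' partial report. \code{load_report} reconstructs the tables.
#'
#' @param report A \code{pipeline_report}.
#' @param dir Output directory (created if missing).
#' @return \code{write_report} returns \code{dir} invisibly;
#'   \code{load_report} returns a list of the tables and the summary.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "pipeline_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  put_csv <- function(df, name) {
    if (is.null(df)) return()
    tmp <- file.path(dir, paste0(".", name, ".tmp"))
    num <- vapply(df, is.numeric, logical(1))
    out <- df
    for (j in which(num)) out[[j]] <- sprintf("%.17g", out[[j]])
    utils::write.csv(out, tmp, row.names = FALSE, quote = FALSE)
    file.rename(tmp, file.path(dir, paste0(name, ".csv")))
  }
  put_csv(report$cv, "model_comparison")
  put_csv(report$sensitivity, "sensitivity")
  put_csv(report$optimization, "optimization")
  hist_rows <- list()
  for (tr in names(report$optim_results)) {
    for (r in report$optim_results[[tr]]$results) {
      if (inherits(r, "error")) next
      hist_rows[[length(hist_rows) + 1]] <- data.frame(
        trait = tr, algorithm = r$algorithm,
        generation = seq_along(r$history), best_f = r$history)
    }
  }
  put_csv(do.call(rbind, hist_rows), "convergence")
  summ <- list(container = "cultivopt-report", version = 1L,
               chosen = as.list(report$chosen),
               seeds = as.list(report$seeds),
               errors = report$errors,
               config = report$config[c("traits", "families", "cv_k",
                                        "cv_repeats", "cv_seed",
                                        "mf_per_input", "seed")],
               optim = unclass(report$config$optim))
  tmp <- file.path(dir, ".summary.tmp")
  jsonlite::write_json(summ, tmp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  file.rename(tmp, file.path(dir, "summary.json"))
  invisible(dir)
}

#' @rdname write_report
#' @export
load_report <- function(dir) {
  grab <- function(name) {
    p <- file.path(dir, paste0(name, ".csv"))
    if (file.exists(p)) utils::read.csv(p) else NULL
  }
  list(cv = grab("model_comparison"), sensitivity = grab("sensitivity"),
       optimization = grab("optimization"), convergence = grab("convergence"),
       summary = jsonlite::read_json(file.path(dir, "summary.json"),
                                     simplifyVector = TRUE))
}
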