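# Packaged growth dataset and design-matrix plumbing.

#' Growth trait and input-variable names
#'
#' Fixed name and column orderings used throughout the package. Inputs are
#' always ordered (blue, red, white, far_red, sucrose); traits are always
#' ordered (shoot_length, root_length, node_number, shoot_number,
#' canopy_area). All downstream indices (design matrices, sensitivity ranks,
#' optimizer bounds) rely on these orderings being constant.
#'
#' @return A character vector of names.
#' @export
growth_traits <- function() {
  c("shoot_length", "root_length", "node_number", "shoot_number",
    "canopy_area")
}

#' @rdname growth_traits
#' @export
growth_inputs <- function() {
  c("blue", "red", "white", "far_red", "sucrose")
}

#' Input-variable bounds of the culture design space
#'
#' Each light channel (blue, red, white, far-red) spans 0--100 umol/m^2/s of
#' photon flux; sucrose spans 1--6 percent (w/v). These are the box bounds
#' used both for validation and as the default optimization domain.
#'
#' @return A 2 x 5 matrix with rows \code{lower}, \code{upper} and one column
#'   per input variable.
#' @export
input_bounds <- function() {
  b <- rbind(lower = c(0, 0, 0, 0, 1),
             upper = c(100, 100, 100, 100, 6))
  colnames(b) <- growth_inputs()
  b
}

trait_units <- function() {
  c(shoot_length = "mm", root_length = "mm", node_number = "count",
    shoot_number = "count", canopy_area = "mm^2")
}

dataset_columns <- function() {
  tr <- growth_traits()
  c(growth_inputs(), as.vector(rbind(paste0("mean_", tr), paste0("se_", tr))),
    "n")
}

#' Load the packaged 66-treatment growth dataset
#'
#' The packaged fixture holds the in vitro Cannabis ('UP-802') growth
#' experiment: 22 light-spectrum treatments (combinations of blue, red,
#' white and far-red irradiance) crossed with 3 sucrose concentrations
#' (1, 3, 6 % w/v), giving 66 treatments of 4 replicate plantlets each
#' (264 plantlets). Each record carries the treatment-level mean and
#' standard error of five growth traits measured after 6 weeks of culture:
#' shoot length (mm), root length (mm), node number, shoot number and
#' canopy surface area (mm^2).
#'
#' @return A \code{growth_dataset}: a data frame with one row per treatment,
#'   input columns \code{blue, red, white, far_red, sucrose}, paired
#'   \code{mean_<trait>} / \code{se_<trait>} columns for the five traits, and
#'   a replicate count column \code{n}.
#' @examples
#' d <- growth_data()
#' nrow(d)           # 66 treatments
#' sum(d$n)          # 264 plantlets
#' @export
growth_data <- function() {
  path <- system.file("extdata", "growth_table.csv", package = "cultivopt")
  if (!nzchar(path) || !file.exists(path)) {
    stop("packaged fixture 'extdata/growth_table.csv' is missing or the ",
         "package is not installed correctly")
  }
  read_growth_csv(path)
}

new_growth_dataset <- function(df) {
  class(df) <- c("growth_dataset", "data.frame")
  df
}

#' Validate a growth dataset
#'
#' Checks the column schema, input-variable bounds (irradiance in [0,100],
#' sucrose in [1,6]), non-negative trait means and SEs, positive replicate
#' counts and uniqueness of treatment keys. Errors name the first offending
#' row.
#'
#' @param df A data frame in the wide growth-dataset layout.
#' @return The validated data frame, classed \code{growth_dataset},
#'   invisibly usable downstream.
#' @export
validate_growth_dataset <- function(df) {
  need <- dataset_columns()
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stop("dataset schema error: missing column(s) ",
         paste(missing, collapse = ", "))
  }
  df <- df[, need]
  for (col in need) {
    if (!is.numeric(df[[col]])) {
      stop("dataset schema error: column '", col, "' is not numeric")
    }
  }
  b <- input_bounds()
  for (v in growth_inputs()) {
    bad <- which(df[[v]] < b["lower", v] | df[[v]] > b["upper", v] |
                   !is.finite(df[[v]]))
    if (length(bad) > 0) {
      stop("validation error: '", v, "' out of [", b["lower", v], ",",
           b["upper", v], "] at row ", bad[1])
    }
  }
  for (tr in growth_traits()) {
    bad <- which(df[[paste0("mean_", tr)]] < 0 | df[[paste0("se_", tr)]] < 0)
    if (length(bad) > 0) {
      stop("validation error: negative mean/SE for '", tr, "' at row ",
           bad[1])
    }
  }
  bad <- which(df$n < 1 | df$n != round(df$n))
  if (length(bad) > 0) {
    stop("validation error: replicate count must be a positive integer ",
         "(row ", bad[1], ")")
  }
  dup <- which(duplicated(df[, growth_inputs()]))
  if (length(dup) > 0) {
    stop("validation error: duplicate treatment key at row ", dup[1])
  }
  new_growth_dataset(df)
}

#' Read / write growth datasets as CSV
#'
#' Two plain-text layouts are supported. The wide layout (default) has one
#' row per treatment with \code{mean_<trait>}/\code{se_<trait>} columns. The
#' long layout has one row per treatment x trait with columns
#' \code{blue,red,white,far_red,sucrose,trait,mean,se,n}. Writing then
#' reading either layout reproduces the dataset exactly (values round-trip
#' at full precision).
#'
#' @param path File path.
#' @param dataset A \code{growth_dataset}.
#' @param format \code{"wide"} or \code{"long"}.
#' @return \code{read_growth_csv} returns a validated \code{growth_dataset};
#'   \code{write_growth_csv} returns \code{path} invisibly.
#' @export
read_growth_csv <- function(path) {
  df <- utils::read.csv(path, check.names = TRUE)
  if (all(c("trait", "mean", "se") %in% names(df))) {
    df <- long_to_wide(df)
  }
  validate_growth_dataset(df)
}

#' @rdname read_growth_csv
#' @export
write_growth_csv <- function(dataset, path, format = c("wide", "long")) {
  format <- match.arg(format)
  dataset <- validate_growth_dataset(as.data.frame(dataset))
  out <- if (format == "wide") as.data.frame(dataset) else wide_to_long(dataset)
  # format() would truncate; write full double precision so round-trips are exact
  num <- vapply(out, is.numeric, logical(1))
  for (j in which(num)) out[[j]] <- sprintf("%.17g", out[[j]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

wide_to_long <- function(df) {
  rows <- lapply(growth_traits(), function(tr) {
    data.frame(df[, growth_inputs()], trait = tr,
               mean = df[[paste0("mean_", tr)]],
               se = df[[paste0("se_", tr)]], n = df$n)
  })
  do.call(rbind, rows)
}

long_to_wide <- function(df) {
  need <- c(growth_inputs(), "trait", "mean", "se", "n")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stop("dataset schema error: missing column(s) ",
         paste(missing, collapse = ", "))
  }
  bad <- setdiff(unique(df$trait), growth_traits())
  if (length(bad) > 0) {
    stop("unknown trait name(s) in file: ", paste(bad, collapse = ", "),
         "; valid: ", paste(growth_traits(), collapse = ", "))
  }
  key <- df[!duplicated(df[, growth_inputs()]), growth_inputs(), drop = FALSE]
  wide <- key
  keyid <- do.call(paste, c(key, sep = "\r"))
  dfid <- do.call(paste, c(df[, growth_inputs()], sep = "\r"))
  for (tr in growth_traits()) {
    sub <- df[df$trait == tr, ]
    idx <- match(keyid, dfid[df$trait == tr])
    if (anyNA(idx)) stop("dataset schema error: trait '", tr,
                         "' missing for some treatments")
    wide[[paste0("mean_", tr)]] <- sub$mean[idx]
    wide[[paste0("se_", tr)]] <- sub$se[idx]
  }
  wide$n <- df$n[match(keyid, dfid)]
  rownames(wide) <- NULL
  wide
}

#' Extract a design matrix and target vector for one trait
#'
#' @param dataset A \code{growth_dataset}.
#' @param trait One of \code{growth_traits()}.
#' @return A list with \code{X} (n x 5 numeric matrix, columns in
#'   \code{growth_inputs()} order, rows in dataset order) and \code{y}
#'   (numeric vector of treatment means, in the trait's original units).
#' @export
trait_matrix <- function(dataset, trait) {
  if (length(trait) != 1 || !trait %in% growth_traits()) {
    stop("unknown trait '", trait, "'; valid traits: ",
         paste(growth_traits(), collapse = ", "))
  }
  X <- as.matrix(as.data.frame(dataset)[, growth_inputs()])
  y <- as.data.frame(dataset)[[paste0("mean_", trait)]]
  list(X = X, y = y)
}

#' Per-trait extremes of a growth dataset
#'
#' Reports, for each trait, the largest and smallest observed treatment mean
#' and the treatments attaining them. Ties are broken by the first record in
#' dataset order; zeros count as observed minima.
#'
#' @param dataset A non-empty \code{growth_dataset}.
#' @return A data frame with one row per trait and columns \code{trait},
#'   \code{max}, \code{min}, and the five input levels of the maximizing
#'   (\code{max_<input>}) and minimizing (\code{min_<input>}) treatments.
#' @export
trait_extremes <- function(dataset) {
  df <- as.data.frame(dataset)
  if (nrow(df) == 0) stop("dataset is empty")
  rows <- lapply(growth_traits(), function(tr) {
    y <- df[[paste0("mean_", tr)]]
    i_max <- which.max(y)
    i_min <- which.min(y)
    out <- data.frame(trait = tr, max = y[i_max], min = y[i_min])
    for (v in growth_inputs()) out[[paste0("max_", v)]] <- df[[v]][i_max]
    for (v in growth_inputs()) out[[paste0("min_", v)]] <- df[[v]][i_min]
    out
  })
  do.call(rbind, rows)
}
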