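#' Read a long-format mediated-outcome dataset from CSV
#'
#' Expects a comma-separated, UTF-8, '.'-decimal file with header columns
#' `subject_id,time_index,t,w,z,M,Y` and optionally `Ystar`. Validation
#' reports the first offending row by its line in the file.
#'
#' @param path File path.
#' @param strict_balance Require every subject to have the same number of
#'   rows (default `TRUE`; fitting does not need balance, but the generator
#'   always produces it).
#' @return A validated tibble.
#' @export
read_long_csv <- function(path, strict_balance = TRUE) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  dat <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_long_data(dat, strict_balance = strict_balance)
}

#' @rdname read_long_csv
#' @param data A long-format dataset (e.g. from [generate_dataset()]).
#' @export
write_long_csv <- function(data, path) {
  data <- validate_long_data(data, strict_balance = FALSE)
  readr::write_csv(data, path, progress = FALSE)
  invisible(path)
}

validate_long_data <- function(data, strict_balance = TRUE) {
  need <- c("subject_id", "time_index", "t", "w", "z", "M", "Y")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    abort(paste0("missing column(s): ", paste(miss, collapse = ", ")))
  }
  bad_row <- function(ok, what) {
    if (!all(ok)) {
      abort(sprintf("row %d: %s", which(!ok)[1], what))
    }
  }
  bad_row(data$Y %in% c(0, 1), "Y must be 0 or 1")
  bad_row(data$z %in% c(0, 1), "z must be 0 or 1")
  bad_row(is.finite(data$M), "M must be finite")
  bad_row(is.finite(data$w), "w must be finite")
  w_const <- tapply(data$w, data$subject_id, function(x) diff(range(x)) == 0)
  if (!all(w_const)) {
    abort(sprintf("subject %s: baseline covariate w varies within subject",
                  names(w_const)[!w_const][1]))
  }
  if (strict_balance) {
    counts <- table(data$subject_id)
    expected <- as.integer(names(sort(table(as.integer(counts)),
                                      decreasing = TRUE))[1])
    off <- which(counts != expected)
    if (length(off)) {
      abort(sprintf("subject %s has %d rows; expected %d (use `strict_balance = FALSE` to allow)",
                    names(counts)[off[1]], counts[[off[1]]], expected))
    }
  }
  if ("Ystar" %in% names(data)) {
    bad_row((data$Ystar > 0) == (data$Y == 1), "Y must equal the indicator Ystar > 0")
  }
  as_tibble(data)
}

#' Write canonical example datasets
#'
#' Generates small reference cohorts (probit and logit links, 100 and 500
#' subjects, equal-split total effects of 0.3 and 0.4 respectively) as CSV,
#' plus a JSON manifest recording the exact generative parameters and seeds.
#' Used by the documentation and as end-to-end test inputs.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Base seed; fixture seeds are derived from it deterministically.
#' @return Invisibly, the written file paths.
#' @export
make_fixtures <- function(out_dir, seed = 20120124) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  grid <- expand.grid(link = c("probit", "logit"), n = c(100L, 500L),
                      stringsAsFactors = FALSE)
  paths <- character(0)
  manifest <- list()
  for (i in seq_len(nrow(grid))) {
    link <- grid$link[i]; n <- grid$n[i]
    eff <- if (link == "probit") 0.3 else 0.4
    params <- make_scenario(link, eff, "equal")
    fseed <- replicate_seed(seed, i)
    d <- generate_dataset(params, study_design(n), seed = fseed)
    f <- file.path(out_dir, sprintf("%s_n%d.csv", link, n))
    write_long_csv(d, f)
    paths <- c(paths, f)
    manifest[[sprintf("%s_n%d", link, n)]] <- list(
      link = link, n_subjects = n, total_effect = eff, distribution = "equal",
      seed = fseed,
      params = params[c("kappa", "gamma1", "lambda", "theta", "gamma2",
                        "alpha1", "alpha2", "alpha3")],
      psi = as.vector(params$psi))
  }
  mf <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(paths, mf))
}
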