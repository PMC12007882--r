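#' Read a plain-text metabolite id list
#'
#' One id per line; `#` starts a comment; blank lines ignored.
#'
#' @param path file path.
#' @return Character vector of ids.
#' @export
read_id_list <- function(path) {
  if (!file.exists(path)) stop("id list not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines[nzchar(lines)]
}

#' Assemble a results document
#'
#' The machine-readable record of one inference run: tool version, effective
#' configuration, the normalization report, one record per solution, the
#' diversity statistics and the termination status.
#'
#' @param problem the [seed_problem()] that was solved.
#' @param solutions the `seed_solution_set` an engine returned.
#' @param config named list echoing the effective run configuration.
#' @return A list of class `results_document`, ready for
#'   [write_results_json()].
#' @export
results_document <- function(problem, solutions, config = list()) {
  stopifnot(inherits(problem, "seed_problem"),
            inherits(solutions, "seed_solution_set"))
  sols <- lapply(solutions$solutions, function(s) {
    list(seeds = as.list(s$seeds),
         ne_valid = s$ne_valid,
         no_accumulation_valid = s$no_accumulation_valid,
         fba_flux = s$fba_flux,
         fba_valid = !is.na(s$fba_flux) &&
           s$fba_flux > problem$validation$flux_epsilon,
         minimality = s$minimality)
  })
  status <- solutions$status
  if (status == "exhausted_without_valid") status <- "exhausted"
  stats <- if (length(solutions$solutions)) {
    st <- compute_solution_stats(solutions, problem$original_net)
    list(n_solutions = st$n_solutions,
         sizes = as.list(unname(st$sizes)),
         union_size = st$union_size,
         union_size_dereplicated = st$union_size_dereplicated,
         n_imported = length(st$imported),
         n_internal = length(st$internal))
  } else NULL
  structure(
    list(tool = "seedkit",
         version = as.character(utils::packageVersion("seedkit")),
         config = config,
         normalization = problem$net$report,
         mode = problem$targets$mode,
         engine = solutions$engine,
         no_accumulation = problem$no_accumulation,
         candidates = length(problem$candidates),
         forced_seeds = as.list(problem$forced_seeds),
         solutions = sols,
         statistics = stats,
         termination = status),
    class = "results_document"
  )
}

#' Write a results document as JSON
#'
#' @param doc a [results_document()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_results_json <- function(doc, path) {
  stopifnot(inherits(doc, "results_document"))
  jsonlite::write_json(unclass(doc), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
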