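# Validate a counts table: required columns, count sanity, ordered times.
# Returns the data as a tibble with canonical column order.
validate_counts <- function(data, line_offset = NULL) {
  required <- c("replicate", "time_h", "n_sampled", "x_engineered")
  missing <- setdiff(required, names(data))
  if (length(missing)) {
    stop("counts table is missing column(s): ", paste(missing, collapse = ", "))
  }
  if (nrow(data) == 0) stop("counts table is empty")
  data <- tibble::as_tibble(data)[required]
  where <- function(i) {
    if (is.null(line_offset)) paste0("row ", i)
    else paste0("line ", i + line_offset)
  }
  bad <- which(data$x_engineered > data$n_sampled |
                 data$x_engineered < 0 | data$n_sampled < 1)
  if (length(bad)) {
    stop("invalid counts (need 0 <= x_engineered <= n_sampled) at ",
         paste(vapply(bad, where, ""), collapse = ", "))
  }
  dup <- duplicated(data[c("replicate", "time_h")])
  if (any(dup)) {
    stop("duplicate (replicate, time_h) rows at ",
         paste(vapply(which(dup), where, ""), collapse = ", "))
  }
  unordered <- unlist(lapply(split(seq_len(nrow(data)), data$replicate),
                             function(ix) {
    ix[c(FALSE, diff(data$time_h[ix]) <= 0)]
  }))
  if (length(unordered)) {
    stop("sampling times must be strictly increasing within a replicate; ",
         "violated at ", paste(vapply(sort(unordered), where, ""),
                               collapse = ", "))
  }
  data
}

#' Read a serial-transfer counts table
#'
#' Reads genotyping counts from delimited text with header columns
#' `replicate`, `time_h`, `n_sampled`, `x_engineered`. Comma and tab
#' dialects are auto-detected; lines starting with `#` (the metadata block
#' written by [write_counts()]) are skipped. The table is validated: counts
#' within `0 <= x <= n`, no duplicate (replicate, time) rows, strictly
#' increasing times per replicate — violations are reported with the file
#' line number.
#'
#' @param path Path to a CSV/TSV file.
#'
#' @return A validated counts tibble, ready for [fit_mle()].
#' @export
read_counts <- function(path) {
  lines <- readLines(path, warn = FALSE)
  n_comment <- 0
  while (n_comment < length(lines) && grepl("^#", lines[n_comment + 1])) {
    n_comment <- n_comment + 1
  }
  if (n_comment >= length(lines)) stop("no data in ", path)
  header <- lines[n_comment + 1]
  delim <- if (grepl("\t", header)) "\t" else ","
  data <- readr::read_delim(path, delim = delim, comment = "#",
                            show_col_types = FALSE, progress = FALSE)
  # data row i sits at file line i + header line + comment block
  validate_counts(data, line_offset = n_comment + 1)
}

#' Write a serial-transfer counts table
#'
#' Writes counts as canonical comma-separated text (stable across
#' write/read round trips). Simulation metadata attached by
#' [simulate_experiment()] is written as a leading `#`-commented key-value
#' block, which [read_counts()] skips.
#'
#' @param data A counts tibble.
#' @param path Output path.
#' @param meta Optional named list written as `# key: value` header lines;
#'   defaults to the table's `"meta"` attribute (design and seed), if any.
#'
#' @return `path`, invisibly.
#' @export
write_counts <- function(data, path, meta = attr(data, "meta")) {
  data <- validate_counts(data)
  header <- character()
  if (!is.null(meta)) {
    kv <- list(
      seed = meta$seed,
      transfer_interval = meta$design$transfer_interval,
      beta = meta$design$beta, n = meta$design$n,
      replicates = meta$design$replicates, duration = meta$design$duration,
      initial_size = meta$design$initial_size,
      initial_revertants = meta$design$initial_revertants,
      truncation_freq = meta$design$truncation_freq,
      truncated = if (!is.null(meta$truncated))
        paste(meta$truncated, collapse = ",")
    )
    kv <- kv[!vapply(kv, is.null, logical(1))]
    header <- sprintf("# %s: %s", names(kv),
                      vapply(kv, function(v) paste(format(v), collapse = ","),
                             ""))
  }
  body <- readr::format_csv(data)
  writeLines(c(header, sub("\n$", "", body)), path)
  invisible(path)
}

#' Read a run configuration file
#'
#' Reads a YAML run configuration (engine, assumed growth rate, p0 policy,
#' design block, seed, output paths) as used by the command-line interface
#' in `inst/cli/transloss.R`. Design fields are passed to
#' [transfer_design()].
#'
#' @param path Path to a YAML file.
#' @return A named list; the `design` element, if present, is a
#'   [transfer_design()].
#' @export
read_run_config <- function(path) {
  # identity bool handlers keep short keys like "n" as strings (YAML 1.1
  # would otherwise resolve the key n to FALSE)
  cfg <- yaml::read_yaml(path, handlers = list("bool#yes" = identity,
                                               "bool#no" = identity))
  if (!is.null(cfg$design)) {
    cfg$design <- do.call(transfer_design, cfg$design)
  }
  cfg
}
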