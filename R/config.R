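#' Read vital rates from a configuration file
#'
#' Reads a flat key-value configuration (JSON or YAML, chosen by file
#' extension) whose keys are the vital-rate parameter names used
#' throughout the package (`SSf`, `SMf`, ..., `K_L`, optionally `Hf`)
#' and returns a [vital_rates()] object.  Unknown keys raise an error
#' naming the offending field; missing required keys raise the usual
#' constructor error.
#'
#' The installed file `extdata/wild_boar_vital_rates.json` holds the
#' built-in wild boar parameter set in this format and doubles as
#' documentation of the expected keys.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return A [vital_rates()] object.
#' @examples
#' cfg <- system.file("extdata", "wild_boar_vital_rates.json",
#'                    package = "minharmonic")
#' read_vital_rates(cfg)$K_L   # 6
#' @export
read_vital_rates <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  vals <- switch(ext,
    json = jsonlite::fromJSON(path),
    yaml = ,
    yml  = yaml::read_yaml(path),
    stop("unsupported config format '", ext, "' (use json or yaml)",
         call. = FALSE))
  vals <- lapply(vals, as.numeric)
  known <- names(formals(vital_rates))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown vital-rate key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  do.call(vital_rates, vals)
}

#' Write a projection trajectory to CSV
#'
#' Machine-clean CSV (comma separators, header row, `.` decimal mark)
#' with columns `t, fS, fM, fL, mS, mM, mL, Ntot, OSR`.
#'
#' @param x A `"two_sex_projection"` from [project()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(x, path) {
  stopifnot(inherits(x, "two_sex_projection"))
  utils::write.csv(x$trajectory, path, row.names = FALSE)
  invisible(path)
}
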