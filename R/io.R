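#' Load and validate a simulation configuration file
#'
#' Reads a YAML config with blocks `drug`, `formulation`, `systemic` and
#' optionally `physiology` and `simulation`. Every block is passed through
#' the corresponding constructor, so all type invariants are enforced with
#' errors naming the offending field. Omitted physiology fields fall back to
#' the package defaults; the returned bundle records which fields were
#' defaulted. Meal times and the formulation residence time must lie on the
#' `dt` grid.
#'
#' @param path path to a YAML configuration file.
#' @return list with `drug`, `formulation`, `physiology`, `systemic`,
#'   `config` and `provenance` (character vector of defaulted physiology
#'   fields).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  for (block in c("drug", "formulation", "systemic")) {
    if (is.null(raw[[block]])) {
      stop("config is missing required block '", block, "'", call. = FALSE)
    }
  }
  call_ctor <- function(ctor, args, block) {
    ok <- names(formals(ctor))
    bad <- setdiff(names(args), ok)
    if (length(bad)) stop("unknown field(s) in '", block, "': ",
                          paste(bad, collapse = ", "), call. = FALSE)
    tryCatch(do.call(ctor, args),
             error = function(e) stop("invalid '", block, "' block: ",
                                      conditionMessage(e), call. = FALSE))
  }
  drug <- call_ctor(drug_parameters, raw$drug, "drug")
  formulation <- call_ctor(formulation_parameters, raw$formulation, "formulation")
  systemic <- call_ctor(systemic_parameters, raw$systemic, "systemic")
  phys_given <- if (is.null(raw$physiology)) list() else raw$physiology
  physiology <- call_ctor(physiology_parameters, phys_given, "physiology")
  defaulted <- setdiff(setdiff(names(formals(physiology_parameters)), ""),
                       names(phys_given))
  sim_given <- if (is.null(raw$simulation)) list() else raw$simulation
  config <- call_ctor(simulation_config, sim_given, "simulation")

  off <- function(x) x[abs(x / config$dt - round(x / config$dt)) > 1e-9]
  bad_meals <- off(physiology$meal_times)
  if (length(bad_meals)) {
    stop("meal times not divisible by dt = ", config$dt, ": ",
         paste(bad_meals, collapse = ", "), call. = FALSE)
  }
  if (length(off(physiology$formulation_residence))) {
    stop("formulation_residence not divisible by dt = ", config$dt, call. = FALSE)
  }
  list(drug = drug, formulation = formulation, physiology = physiology,
       systemic = systemic, config = config,
       provenance = c(physiology_defaults = list(defaulted)))
}

#' Write a parameter bundle back to a configuration file
#'
#' Round-trips with [load_config()]: writing a loaded bundle and loading it
#' again reproduces the parameter objects.
#'
#' @param bundle list as returned by [load_config()] (or assembled from the
#'   constructors).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(bundle, path) {
  strip <- function(x) {
    x <- unclass(x)
    x[!vapply(x, is.null, logical(1))]
  }
  drug <- strip(bundle$drug)
  drug$p_uwl <- NULL             # derived quantities recomputed on load
  drug$free_fraction_fed <- NULL
  drug$pka <- as.numeric(drug$pka)
  out <- list(drug = drug,
              formulation = strip(bundle$formulation),
              physiology = strip(bundle$physiology),
              systemic = strip(bundle$systemic),
              simulation = strip(bundle$config))
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' Read a time-series profile from delimited text
#'
#' Expects a CSV with a `time_h` column and either `concentration` (giving a
#' [concentration_time_profile()]) or `dissolved_mg` (giving a
#' [dissolution_profile()]; `dose` and `volume` must then be supplied or
#' present as `# dose:` / `# volume:` header comments). Lines starting with
#' `#` are ignored. Non-monotone times and negative values are reported with
#' their line numbers.
#'
#' @param path input path.
#' @param dose,volume dissolution-vessel dose (mg) and volume (mL), required
#'   for dissolution profiles unless recorded in header comments.
#' @param kind profile kind for concentration profiles.
#' @return a `concentration_time_profile` or `dissolution_profile`.
#' @export
read_profile <- function(path, dose = NULL, volume = NULL,
                         kind = c("observed", "predicted")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("profile file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  comments <- grep("^#", lines, value = TRUE)
  hdr <- function(key) {
    m <- grep(paste0("^#\\s*", key, ":"), comments, value = TRUE)
    if (!length(m)) return(NULL)
    as.numeric(sub(paste0("^#\\s*", key, ":\\s*"), "", m[1]))
  }
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  if (!"time_h" %in% names(df)) {
    stop("profile file ", path, " is missing column 'time_h'", call. = FALSE)
  }
  # data line numbers in the original file (header + comments offset)
  data_lines <- setdiff(which(!grepl("^#", lines) & nzchar(lines)),
                        min(which(!grepl("^#", lines))))
  bad_t <- which(diff(df$time_h) <= 0)
  if (length(bad_t)) {
    stop("times not strictly increasing at line(s) ",
         paste(data_lines[bad_t + 1], collapse = ", "), " of ", path,
         call. = FALSE)
  }
  if ("concentration" %in% names(df)) {
    neg <- which(df$concentration < 0)
    if (length(neg)) stop("negative concentration at line(s) ",
                          paste(data_lines[neg], collapse = ", "), " of ",
                          path, call. = FALSE)
    concentration_time_profile(df$time_h, df$concentration, kind = kind)
  } else if ("dissolved_mg" %in% names(df)) {
    if (is.null(dose)) dose <- hdr("dose")
    if (is.null(volume)) volume <- hdr("volume")
    if (is.null(dose) || is.null(volume)) {
      stop("dissolution profiles need 'dose' and 'volume' (argument or ",
           "'# dose:' / '# volume:' header comment)", call. = FALSE)
    }
    neg <- which(df$dissolved_mg < 0)
    if (length(neg)) stop("negative dissolved amount at line(s) ",
                          paste(data_lines[neg], collapse = ", "), " of ",
                          path, call. = FALSE)
    dissolution_profile(df$time_h, df$dissolved_mg, dose = dose,
                        volume = volume, noisy = TRUE)
  } else {
    stop("profile file ", path,
         " needs a 'concentration' or 'dissolved_mg' column", call. = FALSE)
  }
}

#' Write a time-series profile to delimited text
#'
#' Full floating precision (17 significant digits), with units and metadata
#' recorded as `#` header comments, so write-then-read is lossless.
#'
#' @param profile a `concentration_time_profile` or `dissolution_profile`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  fmt <- function(x) sprintf("%.17g", x)
  if (inherits(profile, "concentration_time_profile")) {
    hdr <- c("# units: time_h = hours, concentration = mg/mL",
             sprintf("# kind: %s", profile$kind))
    body <- c("time_h,concentration",
              paste(fmt(profile$times), fmt(profile$concentrations), sep = ","))
  } else if (inherits(profile, "dissolution_profile")) {
    hdr <- c("# units: time_h = hours, dissolved_mg = mg",
             sprintf("# dose: %.17g", profile$dose),
             sprintf("# volume: %.17g", profile$volume))
    body <- c("time_h,dissolved_mg",
              paste(fmt(profile$times), fmt(profile$dissolved_mg), sep = ","))
  } else {
    stop("unsupported profile object of class ",
         paste(class(profile), collapse = "/"), call. = FALSE)
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}
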