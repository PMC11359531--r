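#' Read and write time-profile CSV files
#'
#' The on-disk dialect is a two-column CSV with a header row
#' (`time,value`); the time unit and value kind are declared by the caller,
#' never inferred from the file.
#'
#' @param path file path.
#' @param kind,unit,label passed to [time_profile()].
#' @return [time_profile()] for the reader; invisibly the path for the
#'   writer.
#' @export
read_profile_csv <- function(path, kind = "concentration",
                             unit = "minutes", label = basename(path)) {
  d <- utils::read.csv(path)
  if (ncol(d) < 2) stop("expected a two-column time,value CSV", call. = FALSE)
  time_profile(d[[1]], d[[2]], kind = kind, unit = unit, label = label)
}

#' @rdname read_profile_csv
#' @param profile a [time_profile()].
#' @export
write_profile_csv <- function(profile, path) {
  utils::write.csv(data.frame(time = profile$times, value = profile$values),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a multi-vessel dissolution run CSV
#'
#' Columns: `time_min`, `vessel`, `component`, `concentration_mg_per_ml`.
#'
#' @param path file path.
#' @param v1,v2,m vessel volume (mL), sample volume (mL) and drug content
#'   (mg) used to convert concentrations to cumulative fractions.
#' @return A `dissolution_run`-shaped list (see [simulate_dissolution()]).
#' @export
read_dissolution_csv <- function(path, v1 = 900, v2 = 3, m) {
  d <- utils::read.csv(path)
  need <- c("time_min", "vessel", "component", "concentration_mg_per_ml")
  if (!all(need %in% names(d))) {
    stop("dissolution CSV needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  vs <- sort(unique(d$vessel))
  vessels <- lapply(vs, function(v) {
    dv <- d[d$vessel == v, ]
    dv <- dv[order(dv$time_min), ]
    time_profile(dv$time_min, dv$concentration_mg_per_ml,
                 kind = "concentration",
                 label = sprintf("%s vessel %s", dv$component[1], v))
  })
  fracs <- t(vapply(vessels, function(p)
    cumulative_dissolution(p$times, p$values, v1, v2, m)$values,
    numeric(length(vessels[[1]]$times))))
  grid <- vessels[[1]]$times
  structure(list(medium = NA_character_, component = d$component[1], m = m,
                 v1 = v1, v2 = v2, vessels = vessels, fractions = fracs,
                 mean_profile = time_profile(grid, colMeans(fracs),
                                             kind = "fraction",
                                             label = d$component[1])),
            class = "dissolution_run")
}

#' Read component specifications from a JSON config
#'
#' One entry per component with fields `name`, `content_per_tablet` (mg),
#' `oral_dose` and `iv_dose` (ug), `solubilities` (mg/mL, keyed by medium),
#' `peff` (cm/s), optional `m0_over_v0` and `censored`.
#'
#' @param path JSON file.
#' @return Named list of [component_spec()] objects.
#' @export
read_components_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  out <- lapply(raw, function(x) {
    component_spec(
      name = x$name, content_per_tablet = x$content_per_tablet,
      oral_dose = x$oral_dose, iv_dose = x$iv_dose,
      solubilities = unlist(x$solubilities), peff = x$peff,
      m0_over_v0 = x$m0_over_v0,
      censored = if (is.null(x$censored)) character() else
        unlist(x$censored))
  })
  stats::setNames(out, vapply(out, `[[`, character(1), "name"))
}
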