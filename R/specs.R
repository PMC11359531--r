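#' Registry of supported dissolution media
#'
#' The six media used in the paddle-method dissolution screen, with their
#' nominal pH. Solubility maps on [component_spec()] objects must use these
#' names.
#' @return Named numeric vector of pH values, names are medium identifiers.
#' @export
media_registry <- function() {
  c(HCl_0.1M = 1.2, acetate_pH4.5 = 4.5, phosphate_pH6.8 = 6.8,
    water = 6.9, FaSSGF = 1.6, `FaSSIF-V2` = 6.5)
}

#' Dissolution medium specification
#'
#' Describes one vessel configuration for the paddle method: medium identity,
#' working volume, per-sample withdrawal volume (replaced after each sampling,
#' which is why the cumulative-dissolution formula carries a correction term),
#' and paddle speed.
#'
#' @param name medium identifier, one of `names(media_registry())`.
#' @param volume working volume V1 in mL (default 900).
#' @param sample_volume withdrawn volume V2 in mL per sampling (default 3);
#'   must be smaller than `volume`.
#' @param paddle_rpm paddle speed, one of 50, 75, 100.
#' @return An object of class `medium_spec`.
#' @export
medium_spec <- function(name, volume = 900, sample_volume = 3,
                        paddle_rpm = 75) {
  reg <- media_registry()
  if (!name %in% names(reg)) {
    stop("unknown medium '", name, "'; known media: ",
         paste(names(reg), collapse = ", "), call. = FALSE)
  }
  if (volume <= 0) stop("volume must be > 0", call. = FALSE)
  if (sample_volume < 0 || sample_volume >= volume) {
    stop("sample_volume must be in [0, volume)", call. = FALSE)
  }
  if (!paddle_rpm %in% c(50, 75, 100)) {
    stop("paddle_rpm must be one of 50, 75, 100", call. = FALSE)
  }
  structure(list(name = name, ph = unname(reg[name]), volume = volume,
                 sample_volume = sample_volume, paddle_rpm = paddle_rpm),
            class = "medium_spec")
}

#' Per-component formulation and biopharmaceutics metadata
#'
#' Holds the quantities needed for dose-number classification and for
#' dose-aware prediction: content per tablet (the weight basis for
#' multi-component integration), administered oral and IV doses, the
#' solubility map across media, and the apparent permeability.
#'
#' @param name component name.
#' @param content_per_tablet mg per tablet.
#' @param oral_dose administered oral dose, ug.
#' @param iv_dose administered IV reference dose, ug.
#' @param solubilities named numeric vector, mg/mL, names from
#'   `media_registry()`. Censored lower-bound values (reported as "> x") are
#'   flagged via `censored`.
#' @param peff apparent permeability, cm/s.
#' @param m0_over_v0 maximum dose strength over 250 mL, mg/mL. Computed from
#'   `content_per_tablet` times `tablets_per_dose` over `v0` when omitted.
#' @param tablets_per_dose tablets in a single administration (default 12).
#' @param v0 glass-of-water volume for the dose number, mL (default 250).
#' @param censored character vector of medium names whose solubility is a
#'   lower bound rather than a measured value.
#' @return An object of class `component_spec`.
#' @export
component_spec <- function(name, content_per_tablet, oral_dose, iv_dose,
                           solubilities, peff, m0_over_v0 = NULL,
                           tablets_per_dose = 12, v0 = 250,
                           censored = character()) {
  num <- c(content_per_tablet, oral_dose, iv_dose, peff, v0)
  if (any(num < 0)) stop("component quantities must be non-negative",
                         call. = FALSE)
  reg <- names(media_registry())
  bad <- setdiff(names(solubilities), reg)
  if (length(bad)) {
    stop("solubility keys not in the media registry: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (is.null(m0_over_v0)) {
    m0_over_v0 <- content_per_tablet * tablets_per_dose / v0
  }
  structure(list(name = name, content_per_tablet = content_per_tablet,
                 oral_dose = oral_dose, iv_dose = iv_dose,
                 solubilities = solubilities, peff = peff,
                 m0_over_v0 = m0_over_v0,
                 tablets_per_dose = tablets_per_dose, v0 = v0,
                 censored = censored),
            class = "component_spec")
}

#' @export
print.component_spec <- function(x, ...) {
  cat(sprintf("<component_spec> %s: %.4f mg/tablet, M0/V0 = %.5g mg/mL, Peff = %.3g cm/s\n",
              x$name, x$content_per_tablet, x$m0_over_v0, x$peff))
  invisible(x)
}
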