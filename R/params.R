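#' Planning parameters
#'
#' All thresholds and constants of the hard and soft planning conditions.
#' Defaults are the planner's clinical reference configuration: a 2 mm
#' safety margin around risk structures, clearance evaluated up to 1 cm,
#' a 15 cm needle, a 25 degree gantry-tilt allowance within a 60 degree
#' maximum insertion angle, an angle-score breakpoint of 0.9 and a
#' sampling rate of 9 candidate points per square millimetre of skin.
#'
#' @param safety_margin mm; paths with less clearance are inadmissible.
#' @param max_eval_distance mm; clearance at or above this saturates the
#'   distance score.
#' @param max_path_length mm; needle length, the hard length limit.
#' @param tilt_angle degrees; angles up to this are rated very good
#'   (score in `[breakpoint, 1]`).
#' @param max_angle degrees; hard limit on the angle to the vertical axis
#'   and the zero of the angle score.
#' @param tilt_quality_breakpoint angle score at `theta == tilt_angle`.
#' @param sampling_density candidate points per mm^2 of skin.
#' @param clearance_r_step mm; radius increment of the incremental
#'   cylinder clearance.
#' @param clearance_backend `"exact"` (segment-to-mesh distance capped at
#'   `max_eval_distance`) or `"incremental"` (stepped cylinder growth).
#'
#' @return a `planning_params` object (named list).
#' @export
#' @examples
#' planning_params()
#' planning_params(sampling_density = 0.05)
planning_params <- function(safety_margin = 2,
                            max_eval_distance = 10,
                            max_path_length = 150,
                            tilt_angle = 25,
                            max_angle = 60,
                            tilt_quality_breakpoint = 0.9,
                            sampling_density = 9,
                            clearance_r_step = 0.25,
                            clearance_backend = c("exact", "incremental")) {
  clearance_backend <- match.arg(clearance_backend)
  p <- list(safety_margin = safety_margin,
            max_eval_distance = max_eval_distance,
            max_path_length = max_path_length,
            tilt_angle = tilt_angle,
            max_angle = max_angle,
            tilt_quality_breakpoint = tilt_quality_breakpoint,
            sampling_density = sampling_density,
            clearance_r_step = clearance_r_step,
            clearance_backend = clearance_backend)
  validate_params(p)
  structure(p, class = "planning_params")
}

validate_params <- function(p) {
  stopifnot(is.numeric(p$safety_margin), is.numeric(p$max_eval_distance))
  if (p$safety_margin < 0 || p$safety_margin >= p$max_eval_distance) {
    stop("need 0 <= safety_margin < max_eval_distance", call. = FALSE)
  }
  if (!(p$tilt_angle > 0 && p$tilt_angle < p$max_angle && p$max_angle <= 90)) {
    stop("need 0 < tilt_angle < max_angle <= 90", call. = FALSE)
  }
  if (!(p$tilt_quality_breakpoint > 0 && p$tilt_quality_breakpoint < 1)) {
    stop("tilt_quality_breakpoint must be in (0, 1)", call. = FALSE)
  }
  if (p$max_path_length <= 0) stop("max_path_length must be positive", call. = FALSE)
  if (p$sampling_density < 0) stop("sampling_density must be non-negative", call. = FALSE)
  if (p$clearance_r_step <= 0) stop("clearance_r_step must be positive", call. = FALSE)
  invisible(p)
}

#' @export
print.planning_params <- function(x, ...) {
  cat("Planning parameters:\n")
  cat(sprintf("  safety margin        %g mm\n", x$safety_margin))
  cat(sprintf("  max eval distance    %g mm\n", x$max_eval_distance))
  cat(sprintf("  max path length      %g mm\n", x$max_path_length))
  cat(sprintf("  tilt / max angle     %g / %g deg\n", x$tilt_angle, x$max_angle))
  cat(sprintf("  angle breakpoint     %g\n", x$tilt_quality_breakpoint))
  cat(sprintf("  sampling density     %g pts/mm^2\n", x$sampling_density))
  cat(sprintf("  clearance backend    %s (r_step %g mm)\n",
              x$clearance_backend, x$clearance_r_step))
  invisible(x)
}

#' Read or write planning parameters as YAML/JSON
#'
#' The file holds a flat mapping mirroring the [planning_params()]
#' arguments; absent fields keep their defaults.
#'
#' @param path file path; format chosen by extension (`.yaml`/`.yml` or
#'   `.json`).
#' @param params a `planning_params` object.
#' @return `read_params()`: a `planning_params`; `write_params()`: the
#'   path, invisibly.
#' @export
read_params <- function(path) {
  raw <- switch(tolower(tools::file_ext(path)),
                "json" = jsonlite::read_json(path, simplifyVector = TRUE),
                yaml::read_yaml(path))
  known <- names(formals(planning_params))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(planning_params, raw)
}

#' @rdname read_params
#' @export
write_params <- function(params, path) {
  x <- unclass(params)
  if (tolower(tools::file_ext(path)) == "json") {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}
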