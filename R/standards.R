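#' Minimum staffing standards
#'
#' A staffing standard gives the minimum number of providers of a cadre that
#' must be present in a department for a shift to count as fully staffed.
#' `default_standards()` returns the standards used for district-level EmONC
#' facilities: at least three nurses/FWVs in the morning and two in each of
#' the evening and night shifts on the ob/gyn and pediatric wards; at least
#' two nurses in every shift of the operating theatre; at least two support
#' staff (any combination of peon/ward boy/aya/sweeper/guard) in every shift;
#' and at least one doctor-style provider per shift.
#'
#' The `department` column `"*"` is a wildcard: a standard with department
#' `"*"` applies to any department that has no exact match for the cadre.
#'
#' @return A tibble with columns `department`, `cadre`, `shift`,
#'   `min_required`.
#' @seealso [read_standards()], [lookup_min_required()]
#' @export
#' @examples
#' default_standards()
default_standards <- function() {
  grid <- function(department, cadre, morning, evening, night) {
    tibble::tibble(
      department = department, cadre = cadre,
      shift = shift_labels(),
      min_required = as.integer(c(morning, evening, night))
    )
  }
  dplyr::bind_rows(
    grid("obgyn_ward", "nurse", 3, 2, 2),
    grid("pediatric_ward", "nurse", 3, 2, 2),
    grid("obgyn_ward", "fwv", 3, 2, 2),
    grid("operating_theatre", "nurse", 2, 2, 2),
    grid("*", "support", 2, 2, 2),
    grid("*", "doctor", 1, 1, 1)
  )
}

#' Look up the minimum required headcount for one cell
#'
#' Resolution order: exact `(department, cadre, shift)` match, then the
#' wildcard department `"*"` for the cadre, then (for doctor-style cadres,
#' where the headcount threshold is nominal) a default of 1. A headcount cadre
#' with no standard is an error: the graded categories are undefined without
#' a minimum.
#'
#' @param standards Tibble as returned by [default_standards()].
#' @param department,cadre,shift Identifiers of the cell.
#' @param mode Cadre payload mode; see [cadre_modes()].
#' @return Integer minimum headcount.
#' @export
lookup_min_required <- function(standards, department, cadre, shift,
                                mode = "graded_headcount") {
  hit <- standards[standards$department == department &
                     standards$cadre == cadre &
                     standards$shift == shift, ]
  if (nrow(hit) == 0) {
    hit <- standards[standards$department == "*" &
                       standards$cadre == cadre &
                       standards$shift == shift, ]
  }
  if (nrow(hit) == 0 && mode == "support_pool") {
    hit <- standards[standards$department == "*" &
                       standards$cadre == "support" &
                       standards$shift == shift, ]
  }
  if (nrow(hit) >= 1) return(as.integer(hit$min_required[[1]]))
  if (mode == "doctor_style") return(1L)
  abort(
    sprintf("no staffing standard for department '%s', cadre '%s', shift '%s'",
            department, cadre, shift),
    class = "emoncavail_missing_standard"
  )
}

#' Read and write staffing standards as YAML
#'
#' The file maps department -> cadre -> shift minimums, e.g.
#'
#' ```yaml
#' obgyn_ward:
#'   nurse: {morning: 3, evening: 2, night: 2}
#' "*":
#'   support: {morning: 2, evening: 2, night: 2}
#' ```
#'
#' @param path Path to a YAML file.
#' @return `read_standards()` returns a standards tibble;
#'   `write_standards()` returns `path` invisibly.
#' @export
read_standards <- function(path) {
  raw <- yaml::read_yaml(path)
  rows <- purrr::imap(raw, function(cadres, department) {
    purrr::imap(cadres, function(mins, cadre) {
      miss <- setdiff(shift_labels(), names(mins))
      if (length(miss) > 0) {
        abort(sprintf("standards for %s/%s missing shifts: %s",
                      department, cadre, paste(miss, collapse = ", ")),
              class = "emoncavail_bad_standards")
      }
      tibble::tibble(
        department = department, cadre = cadre, shift = shift_labels(),
        min_required = as.integer(unlist(mins[shift_labels()]))
      )
    })
  })
  out <- dplyr::bind_rows(purrr::flatten(rows))
  if (any(out$min_required < 1)) {
    abort("minimum required headcounts must be positive",
          class = "emoncavail_bad_standards")
  }
  out
}

#' @rdname read_standards
#' @param standards Standards tibble to serialise.
#' @export
write_standards <- function(standards, path) {
  tree <- list()
  for (dep in unique(standards$department)) {
    sub <- standards[standards$department == dep, ]
    tree[[dep]] <- list()
    for (cad in unique(sub$cadre)) {
      cell <- sub[sub$cadre == cad, ]
      tree[[dep]][[cad]] <- as.list(
        setNames(as.integer(cell$min_required), cell$shift))
    }
  }
  yaml::write_yaml(tree, path)
  invisible(path)
}
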