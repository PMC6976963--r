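#' The 13 sequenced conditions of the cross design
#'
#' The experimental design sequences thirteen pools of 100 females: one shared
#' founder composite sample (`F0`, no line) and, for each insecticide line
#' (`Delt` = deltamethrin, `Bend` = bendiocarb, `Feni` = fenitrothion), the F0
#' survivors of an LD80 exposure (`F0_LD80`), unexposed F2 individuals (`F2`)
#' and F2 survivors of an LD25 and an LD75 exposure (`F2_LD25`, `F2_LD75`).
#'
#' @return A tibble with columns `condition` (unique label), `line`
#'   (`"none"` for the shared F0) and `stage`.
#' @export
#' @examples
#' condition_table()
condition_table <- function() {
  lines <- c("Delt", "Bend", "Feni")
  stages <- c("F0_LD80", "F2", "F2_LD25", "F2_LD75")
  per_line <- tidyr::expand_grid(line = lines, stage = stages)
  dplyr::bind_rows(
    tibble::tibble(line = "none", stage = "F0"),
    per_line
  ) %>%
    dplyr::mutate(condition = condition_label(.data$line, .data$stage)) %>%
    dplyr::select("condition", "line", "stage")
}

#' @rdname condition_table
#' @param line,stage Character vectors; `stage == "F0"` must pair with
#'   `line == "none"`.
#' @export
condition_label <- function(line, stage) {
  ifelse(stage == "F0", "F0", paste(line, stage, sep = "_"))
}

#' @rdname condition_table
#' @export
condition_levels <- function() condition_table()$condition

#' Conditions belonging to one insecticide line
#'
#' Each line's trajectory runs over five conditions: the shared `F0` plus its
#' own `F0_LD80`, `F2`, `F2_LD25` and `F2_LD75`.
#'
#' @param line One of `"Delt"`, `"Bend"`, `"Feni"`.
#' @return Character vector of five condition labels, in stage order.
#' @export
line_conditions <- function(line) {
  line <- match.arg(line, c("Delt", "Bend", "Feni"))
  c("F0", paste(line, c("F0_LD80", "F2", "F2_LD25", "F2_LD75"), sep = "_"))
}

#' @rdname line_conditions
#' @export
line_levels <- function() c("Delt", "Bend", "Feni")

stage_levels <- function() c("F0", "F0_LD80", "F2", "F2_LD25", "F2_LD75")

# Stop unless `conditions` covers all 13 labels; names the absentees.
check_conditions_present <- function(conditions, where = "input") {
  missing <- setdiff(condition_levels(), unique(conditions))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s is missing condition(s): %s", where, paste(missing, collapse = ", ")
    ))
  }
  invisible(TRUE)
}
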