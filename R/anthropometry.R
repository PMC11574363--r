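#' Default 13-segment anthropometric table
#'
#' Segment mass fractions and centre-of-mass positions for the 13-segment
#' whole-body model (bilateral feet, shanks, thighs, upper arms and forearms,
#' plus head, trunk and pelvis), derived from the classic Dempster cadaver
#' coefficients as tabulated by Winter. Each segment is defined by a proximal
#' and a distal marker role; its CoM lies at `com_fraction` of the way from
#' the proximal to the distal endpoint, and it carries `mass_fraction` of
#' total body mass. The forearm fraction includes the hand (no hand markers
#' are required).
#'
#' The shipped defaults live in
#' `system.file("extdata", "anthropometry_dempster.csv", package = "sandgait")`
#' and can be overridden by any table passing [validate_anthropometric_table()].
#'
#' @return A tibble with columns `segment`, `proximal_role`, `distal_role`,
#'   `mass_fraction`, `com_fraction`.
#' @export
#' @examples
#' tab <- default_anthropometric_table()
#' sum(tab$mass_fraction) # 1
default_anthropometric_table <- function() {
  path <- system.file("extdata", "anthropometry_dempster.csv",
                      package = "sandgait")
  tab <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  validate_anthropometric_table(tab)
  tab
}

#' Validate an anthropometric table
#'
#' Checks that mass fractions sum to 1 (within 1e-6), that every
#' `com_fraction` lies in `[0, 1]`, and that the required columns are present.
#'
#' @param table A data frame like [default_anthropometric_table()].
#' @return The table, invisibly, if valid; otherwise an error.
#' @export
validate_anthropometric_table <- function(table) {
  need <- c("segment", "proximal_role", "distal_role",
            "mass_fraction", "com_fraction")
  missing_cols <- setdiff(need, names(table))
  assert_that(length(missing_cols) == 0L,
              paste0("anthropometric table missing column(s): ",
                     paste(missing_cols, collapse = ", ")))
  assert_that(abs(sum(table$mass_fraction) - 1) <= 1e-6,
              sprintf("segment mass fractions must sum to 1 (got %.8f)",
                      sum(table$mass_fraction)))
  assert_that(all(table$com_fraction >= 0 & table$com_fraction <= 1),
              "com_fraction must lie in [0, 1] for every segment")
  assert_that(!anyDuplicated(table$segment),
              "duplicate segment names in anthropometric table")
  invisible(table)
}
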