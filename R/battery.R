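# Test-battery configuration and enumeration.
#
# A battery config is a group label plus rows; each row names a test
# family and the axes to cross: clinical endpoints, genetic models,
# serostatus contrasts (infection tests), breakpoint schemes (categorical
# tests for survival data) and cohort subsets. enumerate_battery() takes
# the cross-product per row and emits one TestDescriptor per combination,
# with a deterministic test_id.

#' Build a battery configuration
#'
#' @param group_id cohort-group label (e.g. `"A"`).
#' @param rows list of [battery_row()] entries.
#' @param expected_total optional integer; [enumerate_battery()] errors if
#'   the enumerated battery size differs.
#' @return list of class `BatteryConfig`.
#' @export
battery_config <- function(group_id, rows, expected_total = NULL) {
  stopifnot(is.character(group_id), is.list(rows))
  structure(list(group_id = group_id, rows = rows,
                 expected_total = expected_total),
            class = "BatteryConfig")
}

#' Define one battery row
#'
#' @param family test family, one of `r toString(TEST_FAMILIES)`.
#' @param endpoints AIDS criteria (progression families), sequelae
#'   conditions (sequelae families) or HAART endpoints; `NULL` for INF
#'   and HWE.
#' @param models genetic models to cross (`"A"` allowed for INF only).
#' @param contrasts serostatus contrasts (INF only), subset of
#'   `r toString(INF_CONTRASTS)`.
#' @param breakpoints list of numeric breakpoint vectors, one per scheme
#'   (PDCA2: length-1 vectors; PDCAM: length >= 2).
#' @param subsets cohort-subset labels (matched against the cohort
#'   table's `cohort` column; `"pooled"` means all samples).
#' @param expected_count optional integer checked against the enumerated
#'   count for this row.
#' @return list of class `battery_row`.
#' @export
battery_row <- function(family, endpoints = NULL, models = "CD",
                        contrasts = NULL, breakpoints = NULL,
                        subsets = NULL, expected_count = NULL) {
  if (!family %in% TEST_FAMILIES) stop("unknown family: ", family)
  if (family == "INF" && is.null(contrasts))
    stop("INF rows require contrasts")
  if (!is.null(contrasts) && !all(contrasts %in% INF_CONTRASTS))
    stop("unknown contrast(s): ",
         paste(setdiff(contrasts, INF_CONTRASTS), collapse = ", "))
  if (any(models == "A") && family != "INF")
    stop("the allelic model is defined for INF tests only")
  if (!all(models %in% GENETIC_MODELS))
    stop("unknown model(s): ", paste(setdiff(models, GENETIC_MODELS), collapse = ", "))
  if (family %in% c("PDCA2", "PDCAM")) {
    if (is.null(breakpoints)) stop(family, " rows require breakpoints")
    len <- lengths(breakpoints)
    if (family == "PDCA2" && any(len != 1))
      stop("PDCA2 breakpoint schemes must contain exactly one breakpoint")
    if (family == "PDCAM" && any(len < 2))
      stop("PDCAM breakpoint schemes need at least two breakpoints")
    if (any(unlist(breakpoints) <= 0)) stop("breakpoints must be positive")
  }
  structure(list(family = family, endpoints = endpoints, models = models,
                 contrasts = contrasts, breakpoints = breakpoints,
                 subsets = subsets, expected_count = expected_count),
            class = "battery_row")
}

bp_label <- function(bp) paste0("bp", paste(bp, collapse = "-"))

#' Enumerate a battery configuration into test descriptors
#'
#' Takes the cross-product endpoints x models x contrasts x breakpoint
#' schemes x subsets for each row and concatenates rows in order. Row
#' counts are additive; `expected_count` / `expected_total` mismatches
#' are errors that list the offending enumeration.
#'
#' @param config a [battery_config()].
#' @return data.frame of descriptors: `test_id`, `family`, `stage`,
#'   `model`, `endpoint`, `contrast`, `breakpoints` (comma-separated
#'   years), `subset`, `group_id`.
#' @export
enumerate_battery <- function(config) {
  stopifnot(inherits(config, "BatteryConfig"))
  out <- lapply(config$rows, function(row) {
    axes <- list(
      endpoint = row$endpoints %||% NA_character_,
      model = row$models,
      contrast = row$contrasts %||% NA_character_,
      bp = if (is.null(row$breakpoints)) NA_character_ else
        vapply(row$breakpoints, bp_label, character(1)),
      subset = row$subsets %||% NA_character_)
    grid <- expand.grid(axes, stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE)
    if (!nrow(grid))
      return(data.frame(test_id = character(0), family = character(0),
                        stage = character(0), model = character(0),
                        endpoint = character(0), contrast = character(0),
                        breakpoints = character(0), subset = character(0),
                        group_id = character(0), stringsAsFactors = FALSE))
    ids <- apply(grid, 1, function(g) {
      parts <- c(row$family, g[["endpoint"]], g[["model"]], g[["contrast"]],
                 g[["bp"]], g[["subset"]])
      paste(parts[!is.na(parts)], collapse = "_")
    })
    bps <- if (is.null(row$breakpoints)) rep(NA_character_, nrow(grid)) else
      vapply(row$breakpoints, function(b) paste(b, collapse = ","),
             character(1))[match(grid$bp,
                                 vapply(row$breakpoints, bp_label, character(1)))]
    des <- data.frame(test_id = ids, family = row$family,
                      stage = FAMILY_STAGE[[row$family]],
                      model = grid$model, endpoint = grid$endpoint,
                      contrast = grid$contrast, breakpoints = bps,
                      subset = grid$subset, group_id = config$group_id,
                      stringsAsFactors = FALSE)
    if (!is.null(row$expected_count) && nrow(des) != row$expected_count)
      stop(sprintf(
        "row %s enumerates %d tests, expected %d:\n%s",
        row$family, nrow(des), row$expected_count,
        paste(des$test_id, collapse = "\n")))
    des
  })
  des <- do.call(rbind, out)
  rownames(des) <- NULL
  if (anyDuplicated(des$test_id))
    stop("duplicate test_id enumerated: ",
         des$test_id[anyDuplicated(des$test_id)])
  if (!is.null(config$expected_total) &&
      nrow(des) != config$expected_total)
    stop(sprintf("battery enumerates %d tests, expected %d",
                 nrow(des), config$expected_total))
  des
}

#' The three-group HIV/AIDS study battery
#'
#' Canned battery configurations shaped like the three cohort study
#' groups of the motivating HIV/AIDS meta-analysis: 123 tests for group A
#' (all four disease stages), 144 for group B, 60 for group C (infection
#' and progression only). Where the published test counts imply axes the
#' text does not spell out (e.g. 48 progression survival tests = 4 AIDS
#' criteria x 3 models x 4 cohort subsets), the subsets chosen here are
#' package defaults and fully configurable.
#'
#' @param group `"A"`, `"B"` or `"C"`.
#' @return a [battery_config()].
#' @export
hiv_battery_config <- function(group = c("A", "B", "C")) {
  group <- match.arg(group)
  crit <- AIDS_CRITERIA
  bp2 <- list(7)             # dichotomous progression breakpoint, years
  bpm <- list(c(3, 7, 11))   # multipoint progression breakpoints, years
  phaz_subsets <- list(A = c("pooled", "ALIVE", "MACS", "MHCS"),
                       B = c("pooled", "ALIVE", "MACS", "MHCS"),
                       C = c("pooled", "ALIVE"))[[group]]
  inf <- if (group == "A")
    battery_row("INF", models = "CD", contrasts = INF_CONTRASTS,
                expected_count = 3)
  else
    battery_row("INF", models = c("D", "R", "CD", "A"),
                contrasts = INF_CONTRASTS, expected_count = 12)
  rows <- list(
    inf,
    battery_row("PDCA2", endpoints = crit, models = c("D", "R", "CD"),
                breakpoints = bp2, expected_count = 12),
    battery_row("PDCAM", endpoints = crit, models = c("D", "R", "CD"),
                breakpoints = bpm, expected_count = 12),
    battery_row("PHAZ", endpoints = crit, models = c("D", "R", "CD"),
                subsets = phaz_subsets,
                expected_count = 12 * length(phaz_subsets)))
  if (group %in% c("A", "B")) {
    seq3 <- c("KS", "PCP", "CM")
    rows <- c(rows, list(
      battery_row("SEQC1", endpoints = seq3, models = c("D", "R", "CD"),
                  expected_count = 9)))
    if (group == "A")
      rows <- c(rows, list(
        battery_row("SEQS1", endpoints = seq3, models = c("D", "R", "CD"),
                    expected_count = 9)))
    if (group == "A") {
      rows <- c(rows, list(
        battery_row("SEQCA", endpoints = seq3, models = c("D", "R", "CD"),
                    expected_count = 9),
        battery_row("SEQSA", endpoints = seq3, models = c("D", "R", "CD"),
                    expected_count = 9),
        battery_row("HRTC", endpoints = HAART_ENDPOINTS,
                    models = c("D", "R", "CD"), expected_count = 6),
        battery_row("HRTS", endpoints = HAART_ENDPOINTS,
                    models = c("D", "R", "CD"), expected_count = 6)))
    } else {
      rows <- c(rows, list(
        battery_row("SEQCA", endpoints = SEQUELAE, models = c("D", "R", "CD"),
                    subsets = "pooled", expected_count = 18),
        battery_row("SEQCA", endpoints = SEQUELAE[1:5],
                    models = c("D", "R", "CD"), subsets = "extended",
                    expected_count = 15),
        battery_row("SEQSA", endpoints = c("KS", "PCP"),
                    models = c("D", "R", "CD"), expected_count = 6),
        battery_row("HRTS", endpoints = HAART_ENDPOINTS,
                    models = c("D", "R", "CD"),
                    subsets = c("pooled", "HOMER"), expected_count = 12)))
    }
  }
  totals <- c(A = 123L, B = 144L, C = 60L)
  battery_config(group, rows, expected_total = totals[[group]])
}

#' Read / write battery configurations as YAML
#'
#' @param path YAML file.
#' @return [read_battery_config()] returns a `BatteryConfig`.
#' @export
read_battery_config <- function(path) {
  y <- yaml::read_yaml(path)
  rows <- lapply(y$rows, function(r)
    battery_row(r$family, endpoints = unlist(r$endpoints),
                models = unlist(r$models) %||% "CD",
                contrasts = unlist(r$contrasts),
                breakpoints = if (is.null(r$breakpoints)) NULL else
                  lapply(r$breakpoints, unlist),
                subsets = unlist(r$subsets),
                expected_count = r$expected_count))
  battery_config(y$group_id, rows, expected_total = y$expected_total)
}

#' @rdname read_battery_config
#' @param config a `BatteryConfig`.
#' @export
write_battery_config <- function(config, path) {
  y <- list(group_id = config$group_id,
            expected_total = config$expected_total,
            rows = lapply(config$rows, function(r)
              Filter(Negate(is.null), unclass(r))))
  yaml::write_yaml(y, path)
  invisible(path)
}
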