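#' Load a vocabulary configuration
#'
#' Reads the declarative code dictionary that stands in for the
#' ICD-9 -> SNOMED -> MedDRA vocabulary chain of a full OMOP build: indication
#' code families, exposure drug codes per arm, the mapping from adverse-event
#' diagnosis codes to the six collapsed system-organ-class (SOC) categories,
#' the general and indication-specific exclusion code sets, and the
#' negative-control outcome codes.
#'
#' The six SOC categories collapse seven MedDRA system organ classes:
#' `sensory` absorbs both ear/labyrinth and eye disorder codes.
#'
#' @param path Path to a YAML vocabulary file. Defaults to the dictionary
#'   bundled with the package.
#' @return An object of class `fqad_vocabulary`: a list with elements
#'   `indications`, `exposures`, `soc_map` (tibble `condition_code`, `soc`),
#'   `exclusions`, and `negative_controls`.
#' @examples
#' vocab <- load_vocabulary()
#' soc_of(c("AE_EAR_01", "AE_EYE_01", "466.0"), vocab)
#' @export
load_vocabulary <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "vocabulary.yaml", package = "fqad")
  }
  if (!file.exists(path)) {
    stop("vocabulary file not found: ", path, call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  validate_vocabulary(raw)
}

#' @keywords internal
validate_vocabulary <- function(raw) {
  required <- c("indications", "exposures", "soc_map", "exclusions",
                "negative_controls")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop("vocabulary is missing mandatory set(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }

  soc_levels <- c("peripheral_nervous", "neuropsychiatric", "musculoskeletal",
                  "sensory", "cardiovascular", "skin")
  bad_soc <- setdiff(names(raw$soc_map), soc_levels)
  if (length(bad_soc) > 0) {
    stop("unknown SOC categor(ies): ", paste(bad_soc, collapse = ", "),
         call. = FALSE)
  }
  soc_map <- purrr::imap_dfr(raw$soc_map, function(codes, soc) {
    tibble::tibble(condition_code = as.character(codes), soc = soc)
  })
  dup <- soc_map$condition_code[duplicated(soc_map$condition_code)]
  if (length(dup) > 0) {
    stop("condition code(s) mapped to more than one SOC category: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }

  for (nm in names(raw$indications)) {
    codes <- as.character(raw$indications[[nm]])
    if (length(codes) == 0) {
      stop("indication code set '", nm, "' is empty", call. = FALSE)
    }
    if (anyDuplicated(codes)) {
      stop("duplicate codes within indication set '", nm, "'", call. = FALSE)
    }
  }
  for (arm in c("fq", "az", "st")) {
    if (is.null(raw$exposures[[arm]]) || length(raw$exposures[[arm]]) == 0) {
      stop("exposure code set '", arm, "' is missing or empty", call. = FALSE)
    }
  }

  nc <- as.character(raw$negative_controls)
  if (length(nc) == 0) {
    stop("negative-control code set 'negative_controls' is empty",
         call. = FALSE)
  }
  if (anyDuplicated(nc)) {
    stop("duplicate negative-control codes", call. = FALSE)
  }
  ind_codes <- unlist(raw$indications, use.names = FALSE)
  overlap <- intersect(nc, c(ind_codes, soc_map$condition_code))
  if (length(overlap) > 0) {
    stop("negative-control codes collide with indication/AE codes: ",
         paste(overlap, collapse = ", "), call. = FALSE)
  }
  excl_general <- as.character(raw$exclusions$general_conditions)
  overlap2 <- intersect(excl_general,
                        c(ind_codes, soc_map$condition_code, nc))
  if (length(overlap2) > 0) {
    stop("general exclusion codes collide with other code sets: ",
         paste(overlap2, collapse = ", "), call. = FALSE)
  }

  vocab <- list(
    indications = purrr::map(raw$indications, as.character),
    exposures = purrr::map(raw$exposures, as.character),
    soc_map = soc_map,
    exclusions = raw$exclusions,
    negative_controls = nc
  )
  class(vocab) <- "fqad_vocabulary"
  vocab
}

#' Map diagnosis codes to SOC categories
#'
#' Total lookup: adverse-event codes return one of the six categories
#' (`peripheral_nervous`, `neuropsychiatric`, `musculoskeletal`, `sensory`,
#' `cardiovascular`, `skin`); any other code (indications, exclusions,
#' negative controls, unknowns) returns `NA`.
#'
#' @param code Character vector of diagnosis codes.
#' @param vocab A loaded [load_vocabulary()] object.
#' @return Character vector of SOC categories, `NA` where the code is not an
#'   adverse-event code.
#' @export
soc_of <- function(code, vocab) {
  stopifnot(inherits(vocab, "fqad_vocabulary"))
  vocab$soc_map$soc[match(as.character(code), vocab$soc_map$condition_code)]
}

#' @keywords internal
arm_drug_codes <- function(vocab, arm = c("fq", "azst")) {
  arm <- match.arg(arm)
  if (arm == "fq") vocab$exposures$fq else c(vocab$exposures$az, vocab$exposures$st)
}

#' @export
print.fqad_vocabulary <- function(x, ...) {
  cat("<fqad_vocabulary>\n")
  cat("  indications:", paste(names(x$indications), collapse = ", "), "\n")
  cat("  exposure codes: fq =", length(x$exposures$fq),
      "| az =", length(x$exposures$az), "| st =", length(x$exposures$st), "\n")
  cat("  SOC map:", nrow(x$soc_map), "codes in",
      dplyr::n_distinct(x$soc_map$soc), "categories\n")
  cat("  negative controls:", length(x$negative_controls), "\n")
  invisible(x)
}
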