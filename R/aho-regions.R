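#' AHo region boundaries for VHH domains
#'
#' The AHo numbering scheme places every antibody variable-domain residue in a
#' fixed 149-slot alignment. For heavy-chain-only VHH domains the slots
#' partition into four framework regions and three complementarity-determining
#' regions: FR1 1-26, HCDR1 27-42, FR2 43-56, HCDR2 57-69, FR3 70-107,
#' HCDR3 108-138, FR4 139-149 (all ranges closed).
#'
#' @return A tibble with columns `region`, `start`, `end` (inclusive AHo
#'   positions), one row per region in N- to C-terminal order.
#' @examples
#' aho_regions()
#' @export
aho_regions <- function() {
  tibble::tibble(
    region = c("FR1", "HCDR1", "FR2", "HCDR2", "FR3", "HCDR3", "FR4"),
    start  = c(1L, 27L, 43L, 57L, 70L, 108L, 139L),
    end    = c(26L, 42L, 56L, 69L, 107L, 138L, 149L)
  )
}

#' Number of slots in the AHo alignment
#' @export
AHO_LENGTH <- 149L

# framework region labels, used by hallmark discovery
FRAMEWORK_REGIONS <- c("FR1", "FR2", "FR3", "FR4")

#' Map AHo positions to region labels
#'
#' @param position Integer vector of AHo positions in 1..149.
#' @return Character vector of region labels, one of FR1, HCDR1, FR2, HCDR2,
#'   FR3, HCDR3, FR4.
#' @examples
#' aho_region(c(44, 108)) # "FR2" "HCDR3"
#' @export
aho_region <- function(position) {
  position <- vctrs_int(position, "position")
  if (any(position < 1L | position > AHO_LENGTH)) {
    rlang::abort(sprintf(
      "AHo position out of range 1..%d: %s", AHO_LENGTH,
      paste(position[position < 1L | position > AHO_LENGTH], collapse = ", ")
    ))
  }
  reg <- aho_regions()
  idx <- findInterval(position, reg$start)
  reg$region[idx]
}

#' AHo positions belonging to a region
#'
#' @param region Region label (e.g. `"HCDR3"`).
#' @return Integer vector of AHo positions in the region.
#' @export
aho_positions_of <- function(region) {
  reg <- aho_regions()
  row <- reg[reg$region == region, ]
  if (nrow(row) != 1L) {
    rlang::abort(sprintf("unknown region '%s'", region))
  }
  seq.int(row$start, row$end)
}

# strict integer coercion with an informative error
vctrs_int <- function(x, what) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x != round(x))) {
    rlang::abort(sprintf("`%s` must be finite whole numbers", what))
  }
  as.integer(x)
}
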