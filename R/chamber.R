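#' Open imaging chamber model
#'
#' Bookkeeping model of an open imaging chamber (e.g. an Attofluor-style
#' cell chamber) under fluid exchange. Mixing is assumed perfect and
#' instantaneous; extraction can only draw the chamber down to a residual
#' floor (a thin film always remains over the sample). Fluid infused
#' beyond the working volume spills over the rim; spills are tracked per
#' reagent so volume is conserved exactly:
#' infused - extracted - spilled = net content change.
#'
#' @param working_volume Usable chamber volume, uL.
#' @param residual_floor Minimum volume extraction leaves behind, uL.
#'   Default 10% of the working volume.
#' @param tubing_dead_volume Dead volume of the feed tubing, uL (used by
#'   [overflow_dispense()]).
#' @return An environment of class `fl_chamber`.
#' @export
chamber_model <- function(working_volume = 1000,
                          residual_floor = 0.1 * working_volume,
                          tubing_dead_volume = 50) {
  fl_check(is_number(working_volume) && working_volume > 0,
           "working_volume must be > 0", "fl_invalid_config")
  fl_check(is_number(residual_floor) && residual_floor >= 0 &&
             residual_floor <= working_volume,
           "residual_floor must be in [0, working_volume]", "fl_invalid_config")
  fl_check(is_number(tubing_dead_volume) && tubing_dead_volume >= 0,
           "tubing_dead_volume must be >= 0", "fl_invalid_config")
  ch <- new.env(parent = emptyenv())
  ch$working_volume <- working_volume
  ch$residual_floor <- residual_floor
  ch$tubing_dead_volume <- tubing_dead_volume
  ch$contents <- numeric(0)     # named: reagent -> uL
  ch$spilled <- numeric(0)
  ch$extracted <- numeric(0)
  ch$infused <- numeric(0)
  class(ch) <- "fl_chamber"
  ch
}

#' Total chamber fill
#' @param chamber A [chamber_model()].
#' @return Total volume currently in the chamber, uL.
#' @export
chamber_total <- function(chamber) {
  if (!length(chamber$contents)) 0 else sum(chamber$contents)
}

# Add `volume` uL of `reagent`; anything beyond the working volume spills
# proportionally from the freshly mixed contents.
chamber_add <- function(chamber, reagent, volume) {
  fl_check(is_number(volume) && volume >= 0, "volume must be >= 0")
  if (volume == 0) return(invisible(chamber))
  cur <- chamber$contents
  cur[reagent] <- if (reagent %in% names(cur)) cur[[reagent]] + volume else volume
  chamber$infused[reagent] <-
    (if (reagent %in% names(chamber$infused)) chamber$infused[[reagent]] else 0) + volume
  total <- sum(cur)
  if (total > chamber$working_volume) {
    excess <- total - chamber$working_volume
    frac <- cur / total
    spill <- frac * excess
    cur <- cur - spill
    old <- chamber$spilled
    for (r in names(spill)) {
      old[r] <- (if (r %in% names(old)) old[[r]] else 0) + spill[[r]]
    }
    chamber$spilled <- old
  }
  chamber$contents <- cur
  invisible(chamber)
}

# Remove up to `volume` uL of mixed fluid, never below the residual floor.
# Returns the volume actually removed.
chamber_remove <- function(chamber, volume) {
  fl_check(is_number(volume) && volume >= 0, "volume must be >= 0")
  total <- chamber_total(chamber)
  removable <- max(0, total - chamber$residual_floor)
  take <- min(volume, removable)
  if (take > 0) {
    frac <- chamber$contents / total
    out <- frac * take
    chamber$contents <- chamber$contents - out
    old <- chamber$extracted
    for (r in names(out)) {
      old[r] <- (if (r %in% names(old)) old[[r]] else 0) + out[[r]]
    }
    chamber$extracted <- old
  }
  take
}

#' Delivered volume under overflow loading
#'
#' In overflow loading a small reagent aliquot is pre-loaded into the feed
#' tubing and pushed through with a larger carrier flush. Under the
#' plug-flow model the reagent reaching the chamber is
#' `min(loaded_aliquot, flush_volume)`; once the flush exceeds the aliquot
#' plus the tubing dead volume the whole aliquot is guaranteed delivered.
#'
#' @param loaded_aliquot Reagent volume pre-loaded in the tubing, uL.
#' @param flush_volume Carrier volume pushed behind it, uL.
#' @param chamber A [chamber_model()] (supplies the dead volume; currently
#'   informational under plug flow).
#' @return Delivered reagent volume, uL.
#' @export
#' @examples
#' overflow_dispense(100, 500, chamber_model())  # 100: full aliquot delivered
overflow_dispense <- function(loaded_aliquot, flush_volume,
                              chamber = chamber_model()) {
  fl_check(is_number(loaded_aliquot) && loaded_aliquot >= 0,
           "loaded_aliquot must be >= 0")
  fl_check(is_number(flush_volume) && flush_volume >= 0,
           "flush_volume must be >= 0")
  min(loaded_aliquot, flush_volume)
}
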