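#' Construct a machine specification
#'
#' @param name machine name
#' @param leafBoundaries strictly increasing leaf-pair boundaries (mm at the
#'   isocenter plane); length defines the number of pairs
#' @param maxDoseRate MU/min
#' @param maxGantrySpeed deg/s
#' @param maxLeafSpeed cm/s
#' @param minLeafGap mm; pairs with a gap at or below this are treated as
#'   dosimetrically closed
#' @return a \linkS4class{MachineSpec}
#' @examples
#' ms <- machineSpec("demo", seq(-100, 100, by = 10))
#' ms
#' @export
machineSpec <- function(name, leafBoundaries, maxDoseRate = 600,
                        maxGantrySpeed = 6, maxLeafSpeed = 2.5,
                        minLeafGap = 2) {
  new("MachineSpec", name = name,
      nLeafPairs = length(leafBoundaries) - 1L,
      leafBoundaries = as.numeric(leafBoundaries),
      maxDoseRate = maxDoseRate, maxGantrySpeed = maxGantrySpeed,
      maxLeafSpeed = maxLeafSpeed, minLeafGap = minLeafGap)
}

# Millennium-120-style boundaries: 10 outer 10-mm pairs, 40 central 5-mm
# pairs, 10 outer 10-mm pairs; 60 pairs (120 leaves) spanning 40 cm.
millennium120Boundaries <- function() {
  widths <- c(rep(10, 10), rep(5, 40), rep(10, 10))
  -200 + cumsum(c(0, widths))
}

#' Built-in machine specifications
#'
#' TrueBeam and VitalBeam: 120-leaf (60-pair) Millennium-style MLC, 40 x 40 cm
#' field, 600 MU/min. Halcyon: modeled as a single-layer 57-pair, 5-mm MLC
#' (28.5 cm span), 800 MU/min; its dual-layer geometry is not modeled. All
#' machines use a 2 mm (0.2 cm) minimum leaf gap.
#'
#' @return named list of \linkS4class{MachineSpec}
#' @export
defaultMachines <- function() {
  mb <- millennium120Boundaries()
  hb <- seq(-142.5, 142.5, by = 5)
  list(
    TrueBeam  = machineSpec("TrueBeam",  mb, maxDoseRate = 600),
    VitalBeam = machineSpec("VitalBeam", mb, maxDoseRate = 600),
    Halcyon   = machineSpec("Halcyon",   hb, maxDoseRate = 800)
  )
}

#' Read machine specifications from a YAML config
#'
#' The file maps machine names to fields \code{leaf_boundaries},
#' \code{max_dose_rate}, \code{max_gantry_speed}, \code{max_leaf_speed} and
#' \code{min_leaf_gap}; omitted fields take the \code{\link{machineSpec}}
#' defaults.
#'
#' @param path YAML file
#' @return named list of \linkS4class{MachineSpec}
#' @export
readMachineConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  out <- lapply(names(cfg), function(nm) {
    m <- cfg[[nm]]
    args <- list(name = nm, leafBoundaries = as.numeric(m$leaf_boundaries))
    if (!is.null(m$max_dose_rate)) args$maxDoseRate <- m$max_dose_rate
    if (!is.null(m$max_gantry_speed)) args$maxGantrySpeed <- m$max_gantry_speed
    if (!is.null(m$max_leaf_speed)) args$maxLeafSpeed <- m$max_leaf_speed
    if (!is.null(m$min_leaf_gap)) args$minLeafGap <- m$min_leaf_gap
    do.call(machineSpec, args)
  })
  names(out) <- names(cfg)
  out
}

# Resolve a machine by DICOM TreatmentMachineName; unknown names fall back
# to the TrueBeam geometry with a warning.
resolveMachine <- function(name, machines = defaultMachines()) {
  if (name %in% names(machines)) return(machines[[name]])
  hit <- which(tolower(names(machines)) == tolower(name))
  if (length(hit)) return(machines[[hit[1]]])
  warning("unknown treatment machine '", name,
          "'; using the TrueBeam geometry", call. = FALSE)
  m <- machines[["TrueBeam"]]
  m@name <- name
  m
}
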