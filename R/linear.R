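## Generic linear compartment graphs.
##
## Small hand-built graphs (one- and two-compartment reductions, closed
## subsystems) that run through the same solver as the full maternal-fetal
## model. Useful for analytic-limit verification and teaching examples.

#' Build a generic linear compartment graph
#'
#' Defines a linear mammillary/catenary system by named compartment
#' volumes and first-order transfer clearances. Compartments with `NA`
#' volume are sinks (they accumulate amount and exert no back-pressure).
#' Dosing input goes into `input`.
#'
#' @param volumes Named numeric vector of volumes in L (`NA` = sink).
#' @param transfers Data frame with columns `from`, `to`, `cl` (clearance
#'   in L/h acting on the `from` concentration).
#' @param input Name of the compartment receiving IV input.
#' @return A `compartment_graph` usable with [simulate_pbpk()].
#' @examples
#' g <- linear_graph(c(central = 13), data.frame(from = "central",
#'   to = "urine", cl = 5), input = "central")
#' @export
linear_graph <- function(volumes, transfers, input = names(volumes)[1]) {
  nm <- names(volumes)
  if (!all(c(transfers$from, transfers$to) %in% c(nm, "urine"))) {
    # allow an implicit urine sink
    extra <- setdiff(c(transfers$from, transfers$to), nm)
    if (!all(extra == "urine")) {
      abort("`transfers` reference compartments missing from `volumes`.")
    }
  }
  if (!"urine" %in% nm && "urine" %in% c(transfers$from, transfers$to)) {
    volumes <- c(volumes, urine = NA_real_)
    nm <- names(volumes)
  }
  if (any(transfers$cl < 0)) abort("Transfer clearances must be >= 0.")
  vol_ml <- volumes * 1000
  cl_mlh <- transfers$cl * 1000
  i_from <- match(transfers$from, nm)
  i_to <- match(transfers$to, nm)
  i_input <- match(input, nm)
  n <- length(nm)

  rhs <- function(y, input_rate) {
    conc <- ifelse(is.na(vol_ml), 0, y / vol_ml)
    d <- numeric(n)
    flux <- cl_mlh * conc[i_from]
    for (k in seq_along(flux)) {
      d[i_from[k]] <- d[i_from[k]] - flux[k]
      d[i_to[k]] <- d[i_to[k]] + flux[k]
    }
    d[i_input] <- d[i_input] + input_rate
    d
  }

  structure(
    list(state_names = nm, volumes = vol_ml,
         params = list(pregnant = FALSE, tissues = character(0)),
         plasma_compartment = input, rhs = rhs,
         subject = NULL, drug = list(name = "generic"),
         physiology = NULL, fetal = NULL, rates = NULL),
    class = "compartment_graph"
  )
}
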