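#' Query a rate source at positions
#'
#' @param map a [RateSource-class] (binned map or analytic field).
#' @param x,y coordinates, cm, in the map's own frame.
#' @return firing rates in spikes/s; NA at masked or out-of-grid bins of a
#'   binned map.
#' @export
setGeneric("rateAt", function(map, x, y) standardGeneric("rateAt"))
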