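# Classed conditions used across the package so callers (and the CLI) can
# distinguish validation failures from I/O failures and internal errors.

stop_heshade <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "heshade_error"), call = call))
}

stop_validation <- function(msg, subclass = character()) {
  stop_heshade(msg, c(subclass, "heshade_error_validation"), call = sys.call(-1))
}

stop_colinear <- function(msg) stop_validation(msg, "heshade_error_colinear_points")
stop_out_of_bounds <- function(msg) stop_validation(msg, "heshade_error_out_of_bounds")
stop_duplicate <- function(msg) stop_validation(msg, "heshade_error_duplicate_point")
stop_no_white_area <- function(msg) stop_validation(msg, "heshade_error_no_white_area")
stop_domain <- function(msg) stop_validation(msg, "heshade_error_domain")
stop_shape <- function(msg) stop_validation(msg, "heshade_error_shape")
stop_infeasible <- function(msg) stop_validation(msg, "heshade_error_infeasible")

stop_io <- function(msg) stop_heshade(msg, "heshade_error_io", call = sys.call(-1))
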