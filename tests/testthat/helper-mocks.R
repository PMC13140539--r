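# Mock predictors with analytically known SSR profiles, registered against
# the package's predict_mids() generic so estimation/CI machinery can be
# tested in closed form.

# MID depends linearly on the net flux of R1: exactly quadratic SSR
registerS3method("predict_mids", "mock_linear",
                 function(predictor, flux, conc, ...) {
                   v <- net_fluxes(predictor$network, flux)[["R1"]]
                   out <- list("X:1@1" = c(1 - predictor$k * v, predictor$k * v))
                   attr(out, "out_of_domain") <- FALSE
                   out
                 }, envir = asNamespace("emuflux"))

# MID ignores the fluxes entirely: flat SSR profile
registerS3method("predict_mids", "mock_flat",
                 function(predictor, flux, conc, ...) {
                   out <- list("X:1@1" = c(0.6, 0.4))
                   attr(out, "out_of_domain") <- FALSE
                   out
                 }, envir = asNamespace("emuflux"))
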