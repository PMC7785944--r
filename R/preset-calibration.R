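# Calibrated latent parameter blocks for the named presets, derived with
# calibrate_preset() at its defaults (n = 4e5, 40 damped iterations plus a
# mean/SD polish stage, tail-averaged). The generator rounds, clamps and
# truncates, so the latent scale differs from the observed targets; these
# constants make the *observed* moments, standardized coefficients and
# display-flower correlation of simulated data match the preset targets.
# Regenerate with:  calibrate_preset(population_preset("barra-like"))$latent
.preset_calibration <-
.preset_calibration <-
list(`barra-like` = list(mu = c(corolla_color = 1.22303594375265, 
calyx_color = 1.33661203187381, flowers_total = 15.58256395, 
ovaries_predated = 1.385989975, seeds_per_plant = 247.171887825, 
floral_display = 2.2281365), resid_sd = c(corolla_color = 0.227540684800335, 
calyx_color = 0.093341823207062, flowers_total = 11.6798079116022, 
ovaries_predated = 3.63622656495538, seeds_per_plant = 150.583073583671, 
floral_display = 1.88622319685684), coef = c(cc = 0.200358024454609, 
cf = 20.469596056031, fo = 0.219535648050716, os = -41.0249825112928, 
fs = 26.6992310508057), display_latent_corr = 0.507781160492923), 
    `melide-like` = list(mu = c(corolla_color = 1.14554076640741, 
    calyx_color = 1.43003254305763, flowers_total = 19.613518375, 
    ovaries_predated = 2.851286525, seeds_per_plant = 127.347691225, 
    floral_display = 2.532918725), resid_sd = c(corolla_color = 0.234719063743406, 
    calyx_color = 0.100030725415696, flowers_total = 12.8402840794732, 
    ovaries_predated = 4.14070943652782, seeds_per_plant = 77.7382059293472, 
    floral_display = 2.79100088096029), coef = c(cc = 0, cf = -32.1945773697015, 
    fo = 0.428770804327632, os = 0, fs = 12.5025978388509), display_latent_corr = 0.849169688677476))
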