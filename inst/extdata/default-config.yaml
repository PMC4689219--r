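# Calibrated defaults for the mutual-repression fate switch.
# Concentrations are in arbitrary units scaled so alpha_N/gamma_N = 2;
# time is in hours. All package defaults resolve from this file.
model:
  alpha_N: 1.0        # max NANOG production rate [conc/h]
  alpha_G: 1.0        # max endogenous GATA production rate [conc/h]
  K_GN: 0.3           # repression threshold of total GATA on NANOG [conc]
  K_NG: 0.3           # repression threshold of NANOG on GATA [conc]
  h_N: 4              # Hill exponent, GATA -| NANOG
  h_G: 4              # Hill exponent, NANOG -| GATA
  gamma_N: 0.5        # NANOG degradation [1/h]
  gamma_G: 0.5        # endogenous GATA degradation [1/h]
  gamma_X: 0.5        # exogenous GATA degradation [1/h]
  s: 1.0              # signaling level (0 = none, 1 = saturated)
  K_s: 1.0            # signaling half-effect constant
  m: 2                # signaling Hill exponent
  mode: inhibits_nanog   # none | promotes_gata | inhibits_nanog
protocol:
  t_start: 0.0        # induction pulse onset [h]
  t_end: 6.0          # pulse offset [h]
  t_final: 30.0       # end of chase [h]
population:
  dose_family: lognormal
  dose_location: -1.75   # log-mean; median dose ~ critical dose at s = 1
  dose_scale: 0.8        # log-sd of the induced-dose distribution
  n_cells: 2000
  s_levels: [1.0, 0.5, 0.25]
noise:
  sigma_mult: 0.2     # log-normal multiplicative measurement sd
  background: 0.1     # additive background mean [a.u.] (0.05 * alpha_N/gamma_N)
  background_sd: 0.02
  label_flip: 0.0     # probability an end-point fate label is recorded wrong
analysis:
  frame_interval: 0.25   # time-lapse cadence [h]
  n_boot: 1000
  bandwidth: ~           # null -> Silverman's rule
  prominence_frac: 0.05
  cluster_k: 2
version: "0.1.0"
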