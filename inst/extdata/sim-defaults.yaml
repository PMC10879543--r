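# Default generative parameters for the dyadic-session simulator.
# Units: rates are per second unless suffixed _per_min; durations in seconds.
# Rationale for the main choices lives in the package methods vignette.
schema_version: 1
bin_width_s: 0.2
nominal_duration_s: 600
dismount_threshold_s: 9.4

retrieval:
  # Retrieval latency ~ Exponential(rate = base_rate_per_s * sensitivity),
  # censored at the nominal session length when the caregiver never retrieves.
  base_rate_per_s: 0.02
  # Re-retrieval after a dismount; also scaled by carry motivation.
  re_retrieval_base_rate_per_s: 0.05

carrying:
  # Two-state dwell process while carried: stationary (Holding) vs
  # locomoting (Transport).
  holding_dwell_mean_s: 20
  transport_dwell_mean_s: 6

rejection:
  # Rejection bouts arrive during carrying with hazard
  # hazard_scale_per_s * (1 - tolerance).
  hazard_scale_per_s: 0.010
  bout_mean_s: 1.6
  # Probability that a rejection forces the infant off the carrier.
  forced_prob: 0.62

forced_delay:
  # Forced dismounts lag the rejection end by a truncated exponential on
  # (0, max_s]; max_s is the true change point of the interval distribution.
  mean_s: 4.5
  max_s: 9.4
  min_s: 0.4

voluntary:
  # Spontaneous dismount hazard while carried, scaled up by infant avoidance:
  # hazard = base_hazard_per_s * (1 + avoidance_gain * avoidance).
  base_hazard_per_s: 0.0009
  avoidance_gain: 6

contact:
  # Caregiver contact bouts while the infant is alone after a dismount;
  # each is a cling opportunity the infant refuses with its avoidance
  # probability.
  rate_per_min: 0.8
  bout_mean_s: 3

calls:
  # Baseline infant call rates per context (calls/min). Separation distress
  # drives high rates while alone; contact quiets the infant.
  rates_per_min:
    Alone_BeforeRET: 18
    Holding: 1.5
    Transport: 1.5
    During_Rejection: 6
    Alone_AfterRET: 10
  # Anxiety process while carried: an extra call stream at
  # anxiety_carried_rate_per_min * anxiety_gain * (1 - tolerance),
  # emitting negative (tsik/cry-weighted) calls.
  anxiety_carried_rate_per_min: 8
  call_duration_mean_s: 0.5
  caregiver_rate_per_min: 0.5
  type_mix:
    Alone_BeforeRET: {phee: 0.25, twitter: 0.45, tsik: 0.05, trill: 0.05, cry: 0.15, other: 0.05}
    Holding:         {phee: 0.10, twitter: 0.10, tsik: 0.05, trill: 0.60, cry: 0.05, other: 0.10}
    Transport:       {phee: 0.10, twitter: 0.10, tsik: 0.05, trill: 0.60, cry: 0.05, other: 0.10}
    During_Rejection: {phee: 0.05, twitter: 0.05, tsik: 0.55, trill: 0.05, cry: 0.25, other: 0.05}
    Alone_AfterRET:  {phee: 0.20, twitter: 0.15, tsik: 0.10, trill: 0.05, cry: 0.45, other: 0.05}
  anxiety_mix:       {phee: 0.00, twitter: 0.00, tsik: 0.60, trill: 0.00, cry: 0.40, other: 0.00}
  caregiver_mix:     {phee: 0.50, twitter: 0.40, tsik: 0.00, trill: 0.00, cry: 0.00, other: 0.10}

infant:
  avoidance_base_mean: 0.12
  avoidance_base_sd: 0.05
  anxiety_gain: 1.0

art:
  # Artificial rearing raises baseline avoidance, multiplies alone-context
  # call rates (increasingly past PND 30), and lowers the direct-transfer
  # propensity after PND 12.
  avoidance_boost: 0.25
  alone_call_mult_base: 1.5
  alone_call_slope_per_day: 0.04
  direct_transfer_drop: 0.35
  direct_transfer_pnd: 12

reunion:
  n_bins: 120
  transfer_prob_per_bin: 0.05
  direct_base: 0.85
  direct_pnd_slope_per_day: 0.005
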