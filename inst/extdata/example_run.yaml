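# Example run configuration for run_pipeline()/validate_config().
# A 60-day synthetic spring season at a high-latitude coastal site with a
# songbird arrival step on 2012-03-30.
site:
  name: COVE
  lat: 58.4563
  lon: -135.8660
  utc_offset: -8
season:
  start: 2012-03-01
  end: 2012-04-29
arrival_day: 2012-03-30
rates:
  pre: 2      # songs per hour per species before arrival
  post: 40    # songs per hour per species on/after arrival
noise_floor: -60          # dB re digital full scale
calibration_offset: 90    # dB: full scale -> absolute SPL
seed: 1
stages:
  synth: true
  spl: false          # per-day band-SPL CSVs (large; off by default)
  screen: true
  aci: true
  changepoint: true
  detect: true
  diversity: true
  associate: true
screen:
  low_band_ceiling: 800     # Hz; bands at/below count as weather energy
  threshold_db: 10          # dB above baseline that flags a second
  max_fraction: 0.25        # strict exclusion threshold
aci:
  min_freq: 1250
  max_freq: 6300
changepoint:
  iterations: 10000
  burn_in: 5000
  threshold: 0.5
  p0: 0.2
  w0: 0.2
detector:
  snr_threshold: 10   # dB above running background
  min_duration: 0.1   # s
  max_duration: 2     # s
  min_gap: 0.1        # s; closer events merge
  window_s: 0.05      # STFT frame
  overlap: 0.5
  duration_s: 60      # audio subsample per day for the detection stage
  match_tolerance_s: 1
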