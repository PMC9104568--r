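# Six-pile industrial aerobic-biostabilization campaign.
# Dimensions and probing heights per reactor; sampling design: four
# cross-sections (2.5, 17.5, 32.5, 47.5 m from the fan), 7 probes each,
# weekly cycles. Fan: 3480 rpm, 3800 Pa back pressure, 51 m3/min, 2.64 kW.
fan:
  rotation_per_min: 3480
  back_pressure_Pa: 3800
  delivery_m3_per_min: 51
  power_kW: 2.64
piles:
  - pile_id: A1
    length_m: 50.0
    width_m: 8.1
    height_m: 2.5
    h1_m: 0.625
    h2_m: 1.250
    h3_m: 1.875
    has_sidewalls: false
    n_cycles: 10
    process_days: 69
    initial_mass_Mg: 375
  - pile_id: A2
    length_m: 50.0
    width_m: 8.0
    height_m: 2.1
    h1_m: 0.625
    h2_m: 1.250
    h3_m: 1.800
    has_sidewalls: false
    n_cycles: 9
    process_days: 66
    initial_mass_Mg: 375
  - pile_id: B1
    length_m: 50.0
    width_m: 8.4
    height_m: 2.8
    h1_m: 0.750
    h2_m: 1.500
    h3_m: 2.250
    has_sidewalls: false
    n_cycles: 9
    process_days: 62
    initial_mass_Mg: 650
  - pile_id: B2
    length_m: 50.0
    width_m: 9.0
    height_m: 2.9
    h1_m: 0.750
    h2_m: 1.500
    h3_m: 2.250
    has_sidewalls: false
    n_cycles: 6
    process_days: 44
    initial_mass_Mg: 650
  - pile_id: C1
    length_m: 50.0
    width_m: 8.0
    height_m: 2.6
    h1_m: 0.750
    h2_m: 1.500
    h3_m: 2.250
    has_sidewalls: true
    n_cycles: 6
    process_days: 44
    initial_mass_Mg: 650
  - pile_id: C2
    length_m: 50.0
    width_m: 8.0
    height_m: 2.5
    h1_m: 0.750
    h2_m: 1.500
    h3_m: 2.250
    has_sidewalls: true
    n_cycles: 6
    process_days: 42
    initial_mass_Mg: 650
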