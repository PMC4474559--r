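# 21-territory Caribbean regional definition used for life-expectancy
# aggregation: the UN Caribbean-basin territories with 90,000 or more
# inhabitants, plus Belize and the three Guianas, which share strong
# historical and socio-political links with the island states.
# Membership names only; panel data must be supplied separately.
regions:
  Caribbean:
    members:
      - Antigua and Barbuda
      - Aruba
      - Bahamas
      - Barbados
      - Belize
      - Cuba
      - Curacao
      - Dominican Republic
      - French Guiana
      - Grenada
      - Guadeloupe
      - Guyana
      - Haiti
      - Jamaica
      - Martinique
      - Puerto Rico
      - Saint Lucia
      - Saint Vincent and the Grenadines
      - Suriname
      - Trinidad and Tobago
      - United States Virgin Islands
    notes: >
      21 territories with 90,000+ inhabitants; includes Belize and the
      Guianas alongside the UN island-territory definition.
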