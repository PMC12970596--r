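{
  "endpoint": "https://string-db.org/api/json/network",
  "parameters": {
    "identifiers": "ABCA1%0dACAT1%0dACSL1%0dACSL4%0dAGPS%0dALOX5%0dDGAT1%0dDGAT2%0dFAR1%0dFASN%0dGNPAT%0dGPAM%0dGPCPD1%0dLCAT%0dLIPE%0dLPCAT2%0dLPCAT3%0dLPL%0dPLA2%0dPLA2G4A%0dPLA2G6%0dPLA2G7%0dPLD1%0dPNPLA2%0dTMEM189",
    "species": 9606,
    "required_score": 400,
    "network_type": "full",
    "add_white_nodes": 0,
    "annotation_source": "GO-BP",
    "caller_identity": "lipidfun"
  }
}
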