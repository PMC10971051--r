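item,osia,baha,source
device,15125,8571,prostheses benefit tariff for the implant system
sound_processor,7166,6484,prostheses benefit tariff for a replacement sound processor
surgery,1002,1002,fee schedule items for osseointegration surgery and anaesthesia
hospitalisation,5415,5415,casemix approximation for a minor ENT intervention admission
ae_management,138,138,fee schedule items for initial plus follow-up specialist visits
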