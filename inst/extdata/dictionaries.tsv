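category	surface	canonical
disease	胃部恶性肿瘤	胃癌
disease	直肠Ca	直肠腺癌
disease	结肠Ca	结肠癌
disease	慢性浅表性胃炎	慢性胃炎
drug	草酸铂	奥沙利铂
drug	卡培他滨片	卡培他滨
drug	替加氟注射液	替加氟
drug	5-氟尿嘧啶	氟尿嘧啶
surgery	胃癌根治	胃癌根治术
surgery	根治性胃癌根治术	胃癌根治术
surgery	毕I式吻合	毕I式吻合术
surgery	Miles术	Miles手术
surgery	Dixon术	Dixon手术
test	电子胃镜检查	胃镜检查
test	电子肠镜检查	肠镜检查
test	全腹CT	腹部CT
test	腹部超声	腹部彩超
symptom/sign	上腹部闷痛	上腹闷痛
symptom/sign	恶心感	恶心
symptom/sign	解黑便	黑便
symptom/sign	全身乏力	乏力
body structure	胃体部	胃体
body structure	胃窦部	胃窦
body structure	贲门部	贲门
body structure	直肠部	直肠
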